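# Kaplan-Meier product-limit estimation and log-rank comparison, written
# directly from the estimators' definitions (events precede censorings at
# tied times).

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct observed time t, with n at risk (all subjects with
#' time >= t) and d events at t, the survival multiplies by (1 - d/n);
#' censorings at t leave the curve unchanged and reduce the risk set
#' afterwards (events processed first at ties).
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return data.frame `time`, `at_risk`, `events`, `censored`, `survival`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  stopifnot(all(times >= 0), all(events %in% 0:1),
            length(times) == length(events))
  ut <- sort(unique(times))
  n <- length(times)
  s <- 1
  out <- data.frame(time = ut, at_risk = NA_integer_, events = NA_integer_,
                    censored = NA_integer_, survival = NA_real_)
  for (i in seq_along(ut)) {
    t <- ut[i]
    at_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    c_ <- sum(times == t & events == 0)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$at_risk[i] <- at_risk
    out$events[i] <- d
    out$censored[i] <- c_
    out$survival[i] <- s
  }
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each distinct event time the observed
#' group-1 events are compared with their hypergeometric expectation given
#' the margins, with the hypergeometric variance; the squared standardized
#' sum is referred to chi-square with 1 df. Zero total events (or zero
#' variance) yields p = 1 with a flag.
#'
#' @param times nonnegative follow-up times.
#' @param events 0/1 event indicators.
#' @param group two-level group labels.
#' @return object of class `survival_comparison`: list with `groups`
#'   (sizes), `km` (per-group curves), `chi2`, `p`, `degenerate`.
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly 2 groups")
  stopifnot(length(times) == length(events), length(times) == length(g))
  lev <- levels(g)
  ev_times <- sort(unique(times[events == 1]))
  O1 <- E1 <- V <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    nj <- sum(at_risk)
    n1 <- sum(at_risk & g == lev[1])
    dj <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == lev[1])
    O1 <- O1 + d1
    E1 <- E1 + dj * n1 / nj
    if (nj > 1)
      V <- V + dj * (n1 / nj) * (1 - n1 / nj) * (nj - dj) / (nj - 1)
  }
  degenerate <- length(ev_times) == 0 || V <= 0
  chi2 <- if (degenerate) 0 else (O1 - E1)^2 / V
  p <- if (degenerate) 1 else stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  km <- lapply(stats::setNames(lev, lev), function(l)
    km_estimate(times[g == l], events[g == l]))
  structure(list(groups = stats::setNames(as.integer(table(g)), lev),
                 km = km, chi2 = chi2, p = p, degenerate = degenerate),
            class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("log-rank:", paste(names(x$groups), x$groups, collapse = " vs "),
      sprintf("; chi2 = %.3f, p = %.3g%s\n", x$chi2, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Survival comparison of anchor-loss vs neutral patients, by stratum
#'
#' Runs [logrank_test()] per stratum on overall survival, comparing samples
#' whose band status is in `loss_def` against neutral samples. Strata in
#' which either class falls below `min_per_class` are reported untestable.
#'
#' @param clinical clinical data.frame (`sample_id`, `os_months`,
#'   `os_event`, subtype columns).
#' @param statuses named character vector of anchor-band statuses.
#' @param strata `"all"`, `"pam50"` or `"er_her2"`.
#' @param loss_def statuses counted as loss.
#' @param min_per_class minimum patients per class per stratum (default 5).
#' @return list with `results` (named list of `survival_comparison`) and
#'   `untestable` (stratum labels).
#' @export
survival_by_group <- function(clinical, statuses,
                              strata = c("all", "pam50", "er_her2"),
                              loss_def = c("loss", "deep_loss"),
                              min_per_class = 5) {
  strata <- match.arg(strata)
  cl <- clinical[!is.na(clinical$os_months) & !is.na(clinical$os_event), ]
  st <- statuses[cl$sample_id]
  keep <- st %in% c(loss_def, "neutral")
  cl <- cl[keep, ]; st <- st[keep]
  lab <- ifelse(st %in% loss_def, "loss", "neutral")
  grp <- switch(strata,
                all = rep("all", nrow(cl)),
                pam50 = cl$pam50,
                er_her2 = paste0("ER", cl$er, "/HER2", cl$her2))
  results <- list(); untestable <- character()
  for (lev in sort(unique(grp[!is.na(grp)]))) {
    idx <- which(!is.na(grp) & grp == lev)
    tab <- table(lab[idx])
    if (length(tab) < 2 || min(tab) < min_per_class) {
      untestable <- c(untestable, lev)
      next
    }
    results[[lev]] <- logrank_test(cl$os_months[idx], cl$os_event[idx],
                                   lab[idx])
  }
  list(results = results, untestable = untestable)
}
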