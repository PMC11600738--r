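# Synthetic-cohort generator. Emits every table the pipeline consumes with
# the statistical structure the downstream stages assume: segmental CN
# profiles with intra-band breakpoints, mutations with planted odds ratios
# against the anchor event, dosage-coupled expression, bulk mixtures
# P = SM beta + eps, drug log10 IC50 with planted feature effects, and
# proportional-hazards survival. One global seed expands into fixed
# per-stage child seeds so stages are reproducible in isolation.

STAGE_OFFSETS <- c(cn = 1L, mut = 2L, expr = 3L, mix = 4L, drug = 5L,
                   surv = 6L)

child_seed <- function(cfg, stage) {
  # deterministic, documented derivation; stays below 2^31 - 1
  (as.integer(cfg$seed) %% 65011L) * 33013L + STAGE_OFFSETS[[stage]] * 1009L
}

#' Simulation configuration
#'
#' Bundles every generator parameter with validation. The defaults are the
#' study conditions the pipeline targets: a breast-cancer-scale cohort
#' (1000 samples) in which the anchor cytoband (13q14.2) is heterozygously
#' lost in 44% of samples and homozygously in 1%, mutations planted at odds
#' ratio 4 (co-occurring) and 0.25 (mutually exclusive) against the anchor,
#' a dosage (cis) effect of one log2 unit per copy-number step with unit
#' residual noise, five-cell-type mixtures, ten planted drug-sensitivity
#' interactions of two within-group standard deviations, and a hazard ratio
#' of 2 for anchor loss with 30% censoring.
#'
#' @param seed integer master seed; identical seeds give bit-identical
#'   cohorts.
#' @param n_samples cohort size.
#' @param n_chroms,bands_per_chrom,genes_per_band genome layout (the last
#'   chromosome is labelled "13" so the anchor band exists; bands are
#'   named `q11.2`, `q12.2`, ... so `13q14.2` is the 4th band of chr13).
#' @param band_bp band width in bp.
#' @param mean_segment_bands mean copy-number segment length in bands
#'   (first-order Markov persistence).
#' @param state_probs named probabilities of CN states -2..2 for a fresh
#'   segment.
#' @param breakpoint_rate probability that a band contains a mid-band state
#'   switch (at a uniform random gene index).
#' @param missing_rate per-cell missingness rate of the CN matrix.
#' @param anchor_band band treated as the anchor event.
#' @param anchor_loss_prob,anchor_deep_loss_prob marginal prevalence of
#'   heterozygous and homozygous anchor loss.
#' @param planted_associations data.frame `feature_id`, `odds_ratio`,
#'   `prevalence` of mutation features planted against the anchor.
#' @param n_null_features,null_prevalence independent (null) mutation
#'   features.
#' @param pathogenic_rb1_rate fraction of samples carrying a pathogenic
#'   RB1 mutation (exclusion-rule exercise).
#' @param baseline_mean,baseline_sd per-gene expression baseline
#'   distribution (log2 scale).
#' @param cis_effect expression shift per CN step (log2 units).
#' @param n_trans,trans_effect number and size of trans effects (genes off
#'   the anchor chromosome shifted in anchor-loss samples).
#' @param expr_noise_sd residual expression noise sd.
#' @param n_cell_types,n_marker_genes,dirichlet_conc mixture model layout
#'   and symmetric Dirichlet concentration of the true fractions.
#' @param mix_noise_sd sd of the additive mixture noise (the model's eps).
#' @param sm_noise_sd perturbation sd of the signature-matrix ensemble.
#' @param n_signature_matrices ensemble size (default 10).
#' @param loss_fraction_shift planted shift of the first cell type's
#'   fraction in anchor-loss samples.
#' @param n_cell_lines,n_drugs drug-screen layout.
#' @param anchor_prevalence_cl anchor prevalence among cell lines.
#' @param n_null_features_cl,null_feature_prev_cl additional independent
#'   binary cell-line features.
#' @param n_planted_drugs,planted_drug_effect planted anchor-drug
#'   interactions (log10 IC50 shift in anchor-loss lines).
#' @param drug_resid_sd residual sd of log10 IC50.
#' @param dup_screen_frac fraction of drugs present in both screens.
#' @param baseline_hazard exponential baseline hazard (per month).
#' @param hr_loss hazard ratio of anchor-loss samples.
#' @param censoring_rate target fraction of censored observations.
#' @param pam50_probs named subtype probabilities.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_samples = 1000L,
                       n_chroms = 6L, bands_per_chrom = 8L,
                       genes_per_band = 5L, band_bp = 2e6,
                       mean_segment_bands = 3,
                       state_probs = c(`-2` = 0.01, `-1` = 0.15, `0` = 0.64,
                                       `1` = 0.15, `2` = 0.05),
                       breakpoint_rate = 0.02, missing_rate = 0,
                       anchor_band = "13q14.2",
                       anchor_loss_prob = 0.44, anchor_deep_loss_prob = 0.01,
                       planted_associations = data.frame(
                         feature_id = c("TP53", "PIK3CA"),
                         odds_ratio = c(4, 0.25),
                         prevalence = c(0.3, 0.3)),
                       n_null_features = 20L, null_prevalence = 0.05,
                       pathogenic_rb1_rate = 0.008,
                       baseline_mean = 8, baseline_sd = 2,
                       cis_effect = 1, n_trans = 10L, trans_effect = 1,
                       expr_noise_sd = 1,
                       n_cell_types = 5L, n_marker_genes = 200L,
                       dirichlet_conc = 1, mix_noise_sd = 0.05,
                       sm_noise_sd = 0.1, n_signature_matrices = 10L,
                       loss_fraction_shift = 0.1,
                       n_cell_lines = 52L, n_drugs = 300L,
                       anchor_prevalence_cl = 0.44,
                       n_null_features_cl = 10L, null_feature_prev_cl = 0.2,
                       n_planted_drugs = 10L, planted_drug_effect = -2,
                       drug_resid_sd = 1, dup_screen_frac = 0.1,
                       baseline_hazard = 0.01, hr_loss = 2,
                       censoring_rate = 0.3,
                       pam50_probs = c(LumA = 0.45, LumB = 0.2, Her2 = 0.1,
                                       Basal = 0.15, Normal = 0.1)) {
  cfg <- as.list(environment())
  probs <- c(cfg$breakpoint_rate, cfg$missing_rate, cfg$anchor_loss_prob,
             cfg$anchor_deep_loss_prob, cfg$null_prevalence,
             cfg$pathogenic_rb1_rate, cfg$censoring_rate,
             cfg$anchor_prevalence_cl, cfg$null_feature_prev_cl,
             state_probs, pam50_probs, planted_associations$prevalence)
  if (any(probs < 0 | probs > 1)) stop("config error: probability outside [0,1]")
  if (any(planted_associations$odds_ratio <= 0))
    stop("config error: odds_ratio must be > 0")
  if (cfg$genes_per_band < 1) stop("config error: zero genes per band")
  if (cfg$mean_segment_bands < 1)
    stop("config error: mean segment length < 1 band")
  sds <- c(cfg$baseline_sd, cfg$expr_noise_sd, cfg$mix_noise_sd,
           cfg$sm_noise_sd, cfg$drug_resid_sd)
  if (any(sds < 0)) stop("config error: negative sd")
  if (abs(sum(state_probs) - 1) > 1e-9 || abs(sum(pam50_probs) - 1) > 1e-9)
    stop("config error: state/subtype probabilities must sum to 1")
  if (cfg$anchor_loss_prob + cfg$anchor_deep_loss_prob > 1)
    stop("config error: anchor loss probabilities exceed 1")
  structure(cfg, class = "sim_config")
}

ANCHOR_GENE_NAMES <- c("RB1", "ARL11", "KCNRG", "MIR15A", "MIR16-1")

#' Build the synthetic genome annotation implied by a configuration
#'
#' @param cfg a [sim_config()].
#' @return a [genome_annotation()].
#' @export
build_genome <- function(cfg) {
  chroms <- as.character(seq_len(cfg$n_chroms))
  if (!"13" %in% chroms) chroms[length(chroms)] <- "13"
  bands <- do.call(rbind, lapply(chroms, function(ch) {
    j <- seq_len(cfg$bands_per_chrom)
    data.frame(chrom = ch, start = as.integer((j - 1) * cfg$band_bp),
               end = as.integer(j * cfg$band_bp),
               band_name = sprintf("%sq%d.2", ch, 10L + j),
               stain = rep_len(c("gneg", "gpos50"), length(j)),
               stringsAsFactors = FALSE)
  }))
  # genes are emitted band-by-band in the bands' sorted order; the CN
  # simulator relies on this grouping
  bands <- bands[order(bands$chrom, bands$start), ]
  rownames(bands) <- NULL
  genes <- do.call(rbind, lapply(seq_len(nrow(bands)), function(bi) {
    b <- bands[bi, ]
    g <- cfg$genes_per_band
    w <- (b$end - b$start) / g
    start <- as.integer(b$start + (seq_len(g) - 1) * w + w / 4)
    ids <- sprintf("G%s_%02d_%d", b$chrom,
                   match(b$band_name, bands$band_name), seq_len(g))
    if (b$band_name == cfg$anchor_band) {
      k <- min(g, length(ANCHOR_GENE_NAMES))
      ids[seq_len(k)] <- ANCHOR_GENE_NAMES[seq_len(k)]
    }
    data.frame(gene_id = ids, chrom = b$chrom, start = start,
               end = as.integer(start + w / 2), stringsAsFactors = FALSE)
  }))
  if (!cfg$anchor_band %in% bands$band_name)
    stop("config error: anchor band ", cfg$anchor_band,
         " not in generated genome")
  genome_annotation(genes, bands)
}

#' Simulate segmental gene-level copy-number profiles
#'
#' Per sample and chromosome, a first-order Markov state process over bands
#' (persistence 1 - 1/mean_segment_bands) emits one CN value per gene;
#' with probability `breakpoint_rate` a band of >= 2 genes contains a state
#' switch at a uniform random gene index (to a different state), producing
#' the mixed bands an ambiguous call detects. The anchor band's state is
#' drawn from the configured marginal (deep loss / loss / neutral) so the
#' anchor-loss prevalence matches the configuration within binomial error.
#'
#' @param cfg a [sim_config()].
#' @return list `cn` (gene x sample integer matrix), `annotation`,
#'   `truth` (list with `band_state` bands x samples, `breakpoint` logical
#'   matrix, `anchor` 0/1 vector by sample).
#' @export
simulate_cn_profiles <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg, "cn"))
  ann <- build_genome(cfg)
  bands <- ann$bands
  states <- as.integer(names(cfg$state_probs))
  p_stay <- 1 - 1 / cfg$mean_segment_bands
  nS <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(nS))
  g <- cfg$genes_per_band
  nB <- nrow(bands)
  band_state <- matrix(NA_integer_, nB, nS,
                       dimnames = list(bands$band_name, sample_ids))
  brk <- matrix(FALSE, nB, nS, dimnames = dimnames(band_state))
  cn <- matrix(NA_integer_, nrow(ann$genes), nS,
               dimnames = list(ann$genes$gene_id, sample_ids))
  gene_band <- rep(seq_len(nB), each = g)
  anchor_idx <- match(cfg$anchor_band, bands$band_name)
  chrom_of_band <- bands$chrom
  for (s in seq_len(nS)) {
    prev_chrom <- ""
    st <- NA_integer_
    for (bi in seq_len(nB)) {
      if (chrom_of_band[bi] != prev_chrom) {
        st <- sample(states, 1, prob = cfg$state_probs)
        prev_chrom <- chrom_of_band[bi]
      } else if (stats::runif(1) >= p_stay) {
        st <- sample(states, 1, prob = cfg$state_probs)
      }
      if (bi == anchor_idx) {
        u <- stats::runif(1)
        st <- if (u < cfg$anchor_deep_loss_prob) -2L
        else if (u < cfg$anchor_deep_loss_prob + cfg$anchor_loss_prob) -1L
        else 0L
      }
      band_state[bi, s] <- st
      vals <- rep(st, g)
      if (g >= 2 && stats::runif(1) < cfg$breakpoint_rate) {
        cut <- sample.int(g - 1, 1)
        other <- states[states != st]
        pw <- cfg$state_probs[as.character(other)]
        vals[(cut + 1):g] <- sample(other, 1, prob = pw / sum(pw))
        brk[bi, s] <- TRUE
      }
      cn[gene_band == bi, s] <- vals
    }
  }
  if (cfg$missing_rate > 0) {
    mask <- stats::runif(length(cn)) < cfg$missing_rate
    cn[mask] <- NA_integer_
  }
  anchor <- as.integer(band_state[anchor_idx, ] < 0)
  names(anchor) <- sample_ids
  list(cn = cn, annotation = ann,
       truth = list(band_state = band_state, breakpoint = brk,
                    anchor = anchor))
}

# Solve P(feature | anchor = 0) given marginal prevalence, OR and anchor
# prevalence q. Monotone in p0, so a root bracket always exists for
# prevalence in (0, 1).
planted_cell_probs <- function(prevalence, odds_ratio, q) {
  if (prevalence <= 0) return(c(p0 = 0, p1 = 0))
  if (prevalence >= 1) return(c(p0 = 1, p1 = 1))
  f <- function(p0) {
    o0 <- p0 / (1 - p0)
    p1 <- odds_ratio * o0 / (1 + odds_ratio * o0)
    q * p1 + (1 - q) * p0 - prevalence
  }
  lo <- 1e-12; hi <- 1 - 1e-12
  if (f(lo) > 0 || f(hi) < 0)
    stop("infeasible (prevalence, odds_ratio) pair; feasible prevalence ",
         "range is (0, 1) for finite positive odds ratios")
  p0 <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  o0 <- p0 / (1 - p0)
  c(p0 = p0, p1 = odds_ratio * o0 / (1 + odds_ratio * o0))
}

#' Simulate mutation features with planted anchor associations
#'
#' Planted features are drawn from the 2x2 distribution implied by their
#' marginal prevalence and odds ratio against the anchor; null features are
#' independent Bernoulli draws. A configurable fraction of samples
#' additionally carries a pathogenic RB1 mutation (plus some non-pathogenic
#' RB1 missense carriers), so the pathogenic-carrier exclusion rule has
#' something to act on.
#'
#' @param cfg a [sim_config()].
#' @param anchor named 0/1 vector of true anchor status per sample.
#' @return list `features` (samples x features 0/1 matrix), `mutations`
#'   (mutation table data.frame), `truth` (per-feature planted
#'   parameters).
#' @export
simulate_mutations <- function(cfg, anchor) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg, "mut"))
  n <- length(anchor)
  q <- mean(anchor)
  pl <- cfg$planted_associations
  feats <- matrix(0L, n, 0, dimnames = list(names(anchor), NULL))
  truth <- list()
  for (i in seq_len(nrow(pl))) {
    pr <- planted_cell_probs(pl$prevalence[i], pl$odds_ratio[i], q)
    x <- stats::rbinom(n, 1, ifelse(anchor == 1, pr["p1"], pr["p0"]))
    feats <- cbind(feats, x)
    truth[[pl$feature_id[i]]] <- c(odds_ratio = pl$odds_ratio[i],
                                   prevalence = pl$prevalence[i], pr)
  }
  nullnames <- character()
  if (cfg$n_null_features > 0) {
    nullnames <- sprintf("NULLMUT%02d", seq_len(cfg$n_null_features))
    nulls <- matrix(stats::rbinom(n * cfg$n_null_features, 1,
                                  cfg$null_prevalence), n)
    feats <- cbind(feats, nulls)
  }
  colnames(feats) <- c(pl$feature_id, nullnames)
  recs <- do.call(rbind, lapply(colnames(feats), function(f) {
    carriers <- rownames(feats)[feats[, f] == 1]
    if (!length(carriers)) return(NULL)
    data.frame(sample_id = carriers, gene_id = f, class = "missense",
               pathogenic = FALSE, stringsAsFactors = FALSE)
  }))
  rb1_path <- rownames(feats)[stats::runif(n) < cfg$pathogenic_rb1_rate]
  rb1_vus <- setdiff(rownames(feats)[stats::runif(n) < 0.015], rb1_path)
  recs <- rbind(recs,
                if (length(rb1_path))
                  data.frame(sample_id = rb1_path, gene_id = "RB1",
                             class = "nonsense", pathogenic = TRUE,
                             stringsAsFactors = FALSE),
                if (length(rb1_vus))
                  data.frame(sample_id = rb1_vus, gene_id = "RB1",
                             class = "missense", pathogenic = FALSE,
                             stringsAsFactors = FALSE))
  rownames(recs) <- NULL
  list(features = feats, mutations = recs, truth = truth)
}

#' Simulate dosage-coupled expression
#'
#' Expression = per-gene baseline + cis_effect x CN + trans effects +
#' Gaussian noise (log2 scale). Trans effects shift the first `n_trans`
#' genes located off the anchor chromosome by `trans_effect` in
#' anchor-loss samples.
#'
#' @param cfg a [sim_config()].
#' @param cn gene x sample CN matrix.
#' @param annotation the matching [genome_annotation()].
#' @param anchor named 0/1 anchor status.
#' @return list `expression` (matrix), `truth` (`trans_genes`).
#' @export
simulate_expression <- function(cfg, cn, annotation, anchor) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg, "expr"))
  anchor_chrom <- sub("^([0-9XY]+).*$", "\\1", cfg$anchor_band)
  baseline <- stats::rnorm(nrow(cn), cfg$baseline_mean, cfg$baseline_sd)
  cn0 <- cn; cn0[is.na(cn0)] <- 0L
  e <- baseline + cfg$cis_effect * cn0 +
    matrix(stats::rnorm(length(cn), 0, cfg$expr_noise_sd), nrow(cn))
  dimnames(e) <- dimnames(cn)
  off_anchor <- annotation$genes$gene_id[annotation$genes$chrom != anchor_chrom]
  trans_genes <- utils::head(intersect(rownames(e), off_anchor), cfg$n_trans)
  if (length(trans_genes))
    e[trans_genes, ] <- e[trans_genes, ] +
      cfg$trans_effect * rep(anchor[colnames(e)], each = length(trans_genes))
  attr(e, "scale_tag") <- "raw"
  list(expression = e, truth = list(trans_genes = trans_genes))
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = n)
  sweep(x, 2, colSums(x), `/`)  # cell types in rows, draws in columns
}

#' Simulate bulk mixtures under the linear mixing model
#'
#' True fractions beta are symmetric-Dirichlet draws per sample (with an
#' optional planted shift of the first cell type in anchor-loss samples);
#' the bulk profile is `P = SM_true beta + eps` with Gaussian eps. The
#' signature-matrix ensemble consists of nonnegative perturbations of
#' SM_true.
#'
#' @param cfg a [sim_config()].
#' @param sample_ids sample identifiers (columns of P).
#' @param anchor optional named 0/1 vector enabling the planted fraction
#'   shift.
#' @return list `P`, `sm_true`, `sm_list`, `beta` (cell types x samples).
#' @export
simulate_bulk_mixtures <- function(cfg, sample_ids, anchor = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg, "mix"))
  G <- cfg$n_marker_genes; K <- cfg$n_cell_types
  n <- length(sample_ids)
  types <- utils::head(c("Macrophage", "Tcell", "Bcell", "Fibroblast",
                         "Epithelial",
                         sprintf("CellType%d", seq_len(max(0, K - 5)))), K)
  genes <- sprintf("MRK%04d", seq_len(G))
  sm <- matrix(stats::runif(G * K, 0.1, 1), G, K,
               dimnames = list(genes, types))
  block <- rep(seq_len(K), length.out = G)
  for (k in seq_len(K)) sm[block == k, k] <- sm[block == k, k] + 4
  beta <- rdirichlet(n, rep(cfg$dirichlet_conc, K))
  dimnames(beta) <- list(types, sample_ids)
  if (!is.null(anchor) && cfg$loss_fraction_shift != 0) {
    shift <- cfg$loss_fraction_shift * anchor[sample_ids]
    beta[1, ] <- beta[1, ] + shift
    beta <- sweep(beta, 2, colSums(beta), `/`)
  }
  P <- sm %*% beta + matrix(stats::rnorm(G * n, 0, cfg$mix_noise_sd), G)
  dimnames(P) <- list(genes, sample_ids)
  sm_list <- lapply(seq_len(cfg$n_signature_matrices), function(i)
    pmax(sm + matrix(stats::rnorm(G * K, 0, cfg$sm_noise_sd), G), 0))
  list(P = P, sm_true = sm, sm_list = sm_list, beta = beta)
}

#' Simulate a two-screen drug-response dataset
#'
#' Binary cell-line features (the anchor loss plus independent null
#' features); per (drug, screen, cell line) record, log10 IC50 = drug
#' baseline + sum of planted feature effects + Gaussian residual. The
#' first `n_planted_drugs` drugs carry the planted anchor effect; a
#' fraction of drugs is assayed in both screens.
#'
#' @param cfg a [sim_config()].
#' @return list `responses` (data.frame), `features` (cell lines x
#'   features), `truth` (planted drug ids and effect).
#' @export
simulate_drug_response <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg, "drug"))
  cl <- sprintf("CL%03d", seq_len(cfg$n_cell_lines))
  anchor <- stats::rbinom(cfg$n_cell_lines, 1, cfg$anchor_prevalence_cl)
  feats <- matrix(anchor, ncol = 1, dimnames = list(cl, "anchor_loss"))
  if (cfg$n_null_features_cl > 0) {
    nulls <- matrix(stats::rbinom(cfg$n_cell_lines * cfg$n_null_features_cl,
                                  1, cfg$null_feature_prev_cl),
                    cfg$n_cell_lines)
    colnames(nulls) <- sprintf("NULLFEAT%02d", seq_len(cfg$n_null_features_cl))
    feats <- cbind(feats, nulls)
  }
  drugs <- sprintf("DRUG%03d", seq_len(cfg$n_drugs))
  planted <- utils::head(drugs, cfg$n_planted_drugs)
  n_dup <- ceiling(cfg$dup_screen_frac * cfg$n_drugs)
  screen_of <- ifelse(seq_along(drugs) %% 2 == 1, "screen1", "screen2")
  dup_drugs <- utils::tail(drugs, n_dup)
  recs <- list()
  for (di in seq_along(drugs)) {
    d <- drugs[di]
    scr <- if (d %in% dup_drugs) c("screen1", "screen2") else screen_of[di]
    base <- stats::rnorm(1, 0, 1)
    eff <- if (d %in% planted) cfg$planted_drug_effect * anchor else 0
    for (s in scr) {
      recs[[length(recs) + 1L]] <- data.frame(
        cell_line = cl, drug = d, screen = s,
        log10_ic50 = base + eff +
          stats::rnorm(cfg$n_cell_lines, 0, cfg$drug_resid_sd),
        stringsAsFactors = FALSE)
    }
  }
  list(responses = do.call(rbind, recs), features = feats,
       truth = list(planted_drugs = planted,
                    effect = cfg$planted_drug_effect))
}

PAM50_ER <- c(LumA = "+", LumB = "+", Her2 = "-", Basal = "-", Normal = "+")
PAM50_HER2 <- c(LumA = "-", LumB = "-", Her2 = "+", Basal = "-", Normal = "-")

#' Simulate survival and clinical covariates
#'
#' Event times are exponential with hazard `baseline_hazard` multiplied by
#' `hr_loss` for anchor-loss samples; censoring is an independent
#' exponential calibrated so that about `censoring_rate` of baseline-group
#' observations are censored. PAM50 labels are drawn independently and
#' ER/HER2 status follows the subtype.
#'
#' @param cfg a [sim_config()].
#' @param anchor named 0/1 anchor status per sample.
#' @return clinical data.frame (`sample_id`, `pam50`, `er`, `her2`,
#'   `os_months`, `os_event`).
#' @export
simulate_survival <- function(cfg, anchor) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg, "surv"))
  n <- length(anchor)
  rate <- cfg$baseline_hazard * cfg$hr_loss^anchor
  t_ev <- stats::rexp(n, rate)
  t_c <- if (cfg$censoring_rate > 0) {
    rc <- cfg$baseline_hazard * cfg$censoring_rate / (1 - cfg$censoring_rate)
    stats::rexp(n, rc)
  } else rep(Inf, n)
  pam <- sample(names(cfg$pam50_probs), n, replace = TRUE,
                prob = cfg$pam50_probs)
  known <- pam %in% names(PAM50_ER)
  data.frame(sample_id = names(anchor), pam50 = pam,
             er = ifelse(known, PAM50_ER[pam], "+"),
             her2 = ifelse(known, PAM50_HER2[pam], "-"),
             os_months = pmin(t_ev, t_c),
             os_event = as.integer(t_ev <= t_c),
             stringsAsFactors = FALSE)
}

#' Simulate a complete cohort
#'
#' Runs every generator stage under the per-stage child seeds and
#' assembles a [cohort_bundle()] plus the drug and mixture datasets and
#' the full ground truth for parameter-recovery tests. Stages are
#' independent given the ground truth: changing the drug parameters never
#' alters the CN output.
#'
#' @param cfg a [sim_config()].
#' @return list `bundle`, `features`, `mixtures`, `drugs`, `truth`,
#'   `config`.
#' @export
simulate_cohort <- function(cfg) {
  cnr <- simulate_cn_profiles(cfg)
  mut <- simulate_mutations(cfg, cnr$truth$anchor)
  expr <- simulate_expression(cfg, cnr$cn, cnr$annotation, cnr$truth$anchor)
  clin <- simulate_survival(cfg, cnr$truth$anchor)
  mix <- simulate_bulk_mixtures(cfg, colnames(cnr$cn), cnr$truth$anchor)
  drugs <- simulate_drug_response(cfg)
  bundle <- cohort_bundle(cnr$cn, mut$mutations, clin, cnr$annotation,
                          expression = expr$expression)
  list(bundle = bundle, features = mut$features, mixtures = mix,
       drugs = drugs,
       truth = c(cnr$truth,
                 list(mutation = mut$truth,
                      trans_genes = expr$truth$trans_genes,
                      beta = mix$beta,
                      planted_drugs = drugs$truth$planted_drugs,
                      hr_loss = cfg$hr_loss)),
       config = cfg)
}
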