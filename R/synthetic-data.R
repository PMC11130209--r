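#' Simulation configuration for synthetic discovery/validation cohorts
#'
#' Bundles every knob of the synthetic-data generator: the gene universe and
#' pathway database shape, per-cohort sample sizes, planted differential-mean
#' and differential-variance genes, pathway-structured proportional-hazards
#' survival effects, censoring, chemotherapy assignment and a planted
#' risk-group-by-treatment interaction. The defaults emulate a discovery
#' transcriptome cohort of ~150 tumours with matched normals plus smaller
#' validation cohorts shifted gene-wise to mimic platform differences.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_pathways Number of pathway gene sets to generate.
#' @param pathway_size_range Length-2 integer vector, min/max pathway size
#'   (min must be >= 3).
#' @param nesting_fraction Fraction in \[0,1\] of pathways generated as strict
#'   subsets of another pathway, exercising overlap-coefficient collapse.
#' @param n_tumour,n_normal Tumour / normal sample counts per cohort; scalars
#'   are recycled across cohorts, or give one value per cohort.
#' @param n_cohorts Number of cohorts; cohort 1 is the discovery cohort, the
#'   rest are validation cohorts.
#' @param cohort_shift_sd SD (log2 units) of gene-wise additive mean shifts
#'   applied to validation cohorts (discovery is the unshifted reference).
#' @param base_mean,base_mean_sd Mean and SD of per-gene baseline log2
#'   abundance means.
#' @param base_sd Within-group per-gene SD of log2 abundance.
#' @param de_genes Data frame with columns `gene`, `log2fc`: planted
#'   differential-expression effects added to tumour samples.
#' @param dv_genes Data frame with columns `gene`, `sd_multiplier` (> 1):
#'   planted variance inflation in tumour samples.
#' @param prognostic_cps List of `list(cp = <pathway index>, beta = <per-gene
#'   log-hazard coefficient(s)>)`: every gene of the indexed pathway
#'   contributes `beta * z` to the linear predictor (betas recycled).
#' @param baseline_hazard Baseline event rate (events/year).
#' @param censoring_rate Independent exponential censoring rate (events/year);
#'   0 means administrative censoring only.
#' @param followup_horizon Administrative follow-up cut (years).
#' @param chemo_assignment_prob Bernoulli probability of chemotherapy.
#' @param interaction_loghr Treatment log-hazard multiplier applied only to
#'   treated samples in the planted high-risk stratum (linear predictor above
#'   its cohort median); 0 plants no interaction.
#' @param seed Integer seed; generators never read or leave global RNG state.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_pathways = 25,
                       pathway_size_range = c(8L, 15L),
                       nesting_fraction = 0.2,
                       n_tumour = 150,
                       n_normal = 100,
                       n_cohorts = 4,
                       cohort_shift_sd = 0.3,
                       base_mean = 7,
                       base_mean_sd = 1.5,
                       base_sd = 0.5,
                       de_genes = NULL,
                       dv_genes = NULL,
                       prognostic_cps = list(),
                       baseline_hazard = 0.08,
                       censoring_rate = 0.04,
                       followup_horizon = 10,
                       chemo_assignment_prob = 0.5,
                       interaction_loghr = 0,
                       seed = 1L) {
  counts <- c(n_genes = n_genes, n_pathways = n_pathways,
              n_cohorts = n_cohorts)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (length(pathway_size_range) != 2L ||
      pathway_size_range[1] < 3 ||
      pathway_size_range[1] > pathway_size_range[2])
    stop("pathway_size_range must be (min, max) with min >= 3")
  if (any(n_tumour <= 0) || any(n_normal < 0))
    stop("sample counts must be positive (normals may be 0)")
  if (followup_horizon <= 0) stop("followup_horizon must be > 0")
  if (baseline_hazard <= 0 || censoring_rate < 0)
    stop("hazard rates must be positive (censoring may be 0)")
  stop_if_not_scalar_prob(nesting_fraction, "nesting_fraction")
  stop_if_not_scalar_prob(chemo_assignment_prob, "chemo_assignment_prob")
  if (!is.null(de_genes) &&
      !all(c("gene", "log2fc") %in% names(de_genes)))
    stop("de_genes needs columns 'gene' and 'log2fc'")
  if (!is.null(dv_genes)) {
    if (!all(c("gene", "sd_multiplier") %in% names(dv_genes)))
      stop("dv_genes needs columns 'gene' and 'sd_multiplier'")
    if (any(dv_genes$sd_multiplier <= 1))
      stop("dv sd_multiplier must be > 1")
  }
  cfg <- list(
    n_genes = as.integer(n_genes), n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    nesting_fraction = nesting_fraction,
    n_tumour = as.integer(rep_len(n_tumour, n_cohorts)),
    n_normal = as.integer(rep_len(n_normal, n_cohorts)),
    n_cohorts = as.integer(n_cohorts),
    cohort_shift_sd = cohort_shift_sd,
    base_mean = base_mean, base_mean_sd = base_mean_sd, base_sd = base_sd,
    de_genes = de_genes, dv_genes = dv_genes,
    prognostic_cps = prognostic_cps,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    followup_horizon = followup_horizon,
    chemo_assignment_prob = chemo_assignment_prob,
    interaction_loghr = interaction_loghr,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(n) sprintf("g%04d", seq_len(n))

#' Generate a synthetic pathway database
#'
#' Draws named gene sets from the configured gene universe. Non-nested
#' pathways are sampled from the still-unused gene pool while it lasts (so a
#' configuration with `nesting_fraction = 0` and total size at most
#' `n_genes` yields pairwise-disjoint sets); a `nesting_fraction` share are
#' built as strict subsets of a previously drawn pathway to exercise
#' overlap-coefficient collapse downstream.
#'
#' @param config A [sim_config()].
#' @return A `pathway_db`: named list of gene-identifier vectors with
#'   attributes `universe` (all gene ids) and `source`.
#' @export
generate_pathway_db <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pathway_size_range[2] > config$n_genes)
    stop("pathway_size_range max exceeds n_genes")
  universe <- sim_gene_ids(config$n_genes)
  with_seed(config$seed, {
    np <- config$n_pathways
    n_nested <- min(np - 1L, round(config$nesting_fraction * np))
    n_base <- np - n_nested
    sizes <- sample(seq(config$pathway_size_range[1],
                        config$pathway_size_range[2]),
                    np, replace = TRUE)
    sets <- vector("list", np)
    pool <- universe
    for (i in seq_len(n_base)) {
      if (length(pool) >= sizes[i]) {
        idx <- sample(length(pool), sizes[i])
        sets[[i]] <- pool[idx]
        pool <- pool[-idx]
      } else {
        sets[[i]] <- sample(universe, sizes[i])
      }
    }
    for (i in seq_len(n_nested)) {
      parent <- sets[[sample(n_base, 1)]]
      child_size <- if (length(parent) <= 3) length(parent) - 1L else
        sample(3:(length(parent) - 1L), 1)
      sets[[n_base + i]] <- sample(parent, child_size)
    }
    names(sets) <- sprintf("P%03d", seq_len(np))
    sets <- lapply(sets, sort)
    structure(sets, universe = universe, source = "synthetic",
              class = "pathway_db")
  })
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d gene sets (source: %s), sizes %d-%d\n",
              length(x), attr(x, "source") %||% "unknown",
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a block-structured pathway database
#'
#' Builds `n_blocks` groups of pathways where pathways within a block share
#' most of their genes (high overlap coefficient) and blocks are disjoint.
#' Used to verify that overlap-coefficient clustering with silhouette-guided
#' k-selection recovers a planted cluster count.
#'
#' @param n_blocks Number of planted blocks.
#' @param paths_per_block Pathways per block.
#' @param genes_per_block Genes in each block's shared pool.
#' @param frac_shared Fraction of each pathway drawn from the block pool
#'   core (the rest are block-private singletons); 1 makes pathways within a
#'   block subsets of a common core.
#' @param seed Integer seed.
#' @return A `pathway_db` with attribute `block` (planted block label per
#'   pathway).
#' @export
simulate_pathway_blocks <- function(n_blocks, paths_per_block = 4,
                                    genes_per_block = 20,
                                    frac_shared = 0.9, seed = 1L) {
  with_seed(seed, {
    universe <- sprintf("b%02dg%03d", rep(seq_len(n_blocks),
                                          each = genes_per_block),
                        rep(seq_len(genes_per_block), n_blocks))
    sets <- list(); block <- integer(0)
    for (b in seq_len(n_blocks)) {
      pool <- universe[(b - 1) * genes_per_block + seq_len(genes_per_block)]
      core <- pool[seq_len(max(3, round(frac_shared * genes_per_block)))]
      for (j in seq_len(paths_per_block)) {
        sz <- max(3, round(length(core) * stats::runif(1, 0.7, 1)))
        sets[[length(sets) + 1L]] <- sort(sample(core, sz))
        block <- c(block, b)
      }
    }
    names(sets) <- sprintf("B%02d_P%02d", block,
                           stats::ave(block, block, FUN = seq_along))
    structure(sets, universe = universe, source = "synthetic-blocks",
              block = block, class = "pathway_db")
  })
}

#' Generate multi-cohort tumour/normal expression with survival outcomes
#'
#' Normal samples follow per-gene Gaussian baselines on the log2 scale;
#' tumours add planted log2 fold-changes for differential-expression genes
#' and inflated SDs for differential-variance genes. Each tumour sample's
#' linear predictor is the sum of planted per-gene betas times its
#' within-cohort z-scored expression; event times are exponential with rate
#' `baseline_hazard * exp(eta)`, independently censored and administratively
#' cut at the follow-up horizon. Treated samples in the planted high-risk
#' stratum (eta above its cohort median) have their hazard multiplied by
#' `exp(interaction_loghr)`. Cohort 1 is the discovery cohort; validation
#' cohorts receive gene-wise additive mean shifts.
#'
#' @param config A [sim_config()].
#' @param db A `pathway_db` over the same gene universe (required when
#'   `prognostic_cps` is non-empty).
#' @return List with `cohorts` (list of [expression_cohort] objects) and
#'   `truth` (planted DE/DV/prognostic genes, per-cohort high-risk labels,
#'   interaction log-HR, seed).
#' @export
generate_cohorts <- function(config, db = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_ids(config$n_genes)
  prog_beta <- numeric(0)
  if (length(config$prognostic_cps)) {
    if (is.null(db)) stop("db required when prognostic_cps is non-empty")
    for (pc in config$prognostic_cps) {
      cp_genes <- db[[pc$cp]]
      if (!all(cp_genes %in% genes))
        stop("planted prognostic genes must exist in the gene universe")
      b <- rep_len(pc$beta, length(cp_genes))
      prog_beta[cp_genes] <- b
    }
  }
  de <- stats::setNames(numeric(0), character(0))
  if (!is.null(config$de_genes)) {
    if (!all(config$de_genes$gene %in% genes))
      stop("planted DE genes must exist in the gene universe")
    de <- stats::setNames(config$de_genes$log2fc, config$de_genes$gene)
  }
  dv <- stats::setNames(numeric(0), character(0))
  if (!is.null(config$dv_genes)) {
    if (!all(config$dv_genes$gene %in% genes))
      stop("planted DV genes must exist in the gene universe")
    dv <- stats::setNames(config$dv_genes$sd_multiplier, config$dv_genes$gene)
  }

  with_seed(config$seed, {
    mu <- stats::rnorm(config$n_genes, config$base_mean, config$base_mean_sd)
    names(mu) <- genes
    sd_normal <- rep(config$base_sd, config$n_genes)
    sd_tumour <- sd_normal
    sd_tumour[match(names(dv), genes)] <- config$base_sd * dv
    mu_tumour <- mu
    mu_tumour[match(names(de), genes)] <- mu[names(de)] + de

    cohorts <- vector("list", config$n_cohorts)
    high_risk <- vector("list", config$n_cohorts)
    for (ci in seq_len(config$n_cohorts)) {
      nt <- config$n_tumour[ci]; nn <- config$n_normal[ci]
      shift <- if (ci == 1) numeric(config$n_genes) else
        stats::rnorm(config$n_genes, 0, config$cohort_shift_sd)
      tum <- matrix(stats::rnorm(config$n_genes * nt,
                                 mean = mu_tumour + shift, sd = sd_tumour),
                    nrow = config$n_genes, ncol = nt)
      rownames(tum) <- genes
      colnames(tum) <- sprintf("C%d_T%03d", ci, seq_len(nt))
      eta <- numeric(nt)
      if (length(prog_beta)) {
        z <- tum[names(prog_beta), , drop = FALSE]
        z <- (z - rowMeans(z)) / sqrt(row_vars(z))
        eta <- as.numeric(crossprod(z, prog_beta))
      }
      hr_stratum <- eta > stats::median(eta)
      chemo <- stats::rbinom(nt, 1, config$chemo_assignment_prob)
      lin <- eta + config$interaction_loghr * chemo * hr_stratum
      t_event <- stats::rexp(nt, rate = config$baseline_hazard * exp(lin))
      t_cens <- if (config$censoring_rate > 0)
        stats::rexp(nt, rate = config$censoring_rate) else rep(Inf, nt)
      obs <- pmin(t_event, t_cens, config$followup_horizon)
      event <- as.integer(t_event <= t_cens &
                            t_event <= config$followup_horizon)
      clin_t <- data.frame(
        sample = colnames(tum), time = obs, event = event, endpoint = "OS",
        age = round(stats::rnorm(nt, 60, 10)),
        t_stage = sample(c("T1", "T2", "T3"), nt, replace = TRUE,
                         prob = c(0.4, 0.45, 0.15)),
        nodal = stats::rbinom(nt, 1, 0.4),
        purity = stats::runif(nt, 0.2, 0.8),
        chemo = chemo,
        tnbc_or_her2 = stats::rbinom(nt, 1, 0.05),
        stringsAsFactors = FALSE)
      if (nn > 0) {
        nor <- matrix(stats::rnorm(config$n_genes * nn,
                                   mean = mu + shift, sd = sd_normal),
                      nrow = config$n_genes, ncol = nn)
        rownames(nor) <- genes
        colnames(nor) <- sprintf("C%d_N%03d", ci, seq_len(nn))
        clin_n <- data.frame(
          sample = colnames(nor), time = NA_real_, event = NA_integer_,
          endpoint = NA_character_, age = round(stats::rnorm(nn, 55, 10)),
          t_stage = NA_character_, nodal = NA_integer_, purity = NA_real_,
          chemo = NA_integer_, tnbc_or_her2 = NA_integer_,
          stringsAsFactors = FALSE)
        values <- cbind(tum, nor)
        clin <- rbind(clin_t, clin_n)
        is_normal <- c(rep(FALSE, nt), rep(TRUE, nn))
      } else {
        values <- tum; clin <- clin_t; is_normal <- rep(FALSE, nt)
      }
      cohorts[[ci]] <- expression_cohort(
        values, clinical = clin,
        cohort_id = sprintf("cohort%d", ci),
        role = if (ci == 1) "discovery" else "validation",
        is_normal = is_normal)
      high_risk[[ci]] <- stats::setNames(hr_stratum, colnames(tum))
    }
    names(cohorts) <- vapply(cohorts, function(co) co$cohort_id, "")
    truth <- list(
      de_genes = de, dv_genes = dv, prognostic_beta = prog_beta,
      high_risk = stats::setNames(high_risk, names(cohorts)),
      interaction_loghr = config$interaction_loghr, seed = config$seed)
    list(cohorts = cohorts, truth = truth)
  })
}

#' Generate a synthetic CRISPR gene-effect screen
#'
#' Background genes get gene-effect (GE) scores around 0; planted
#' synthetic-lethal genes have group-specific means (more negative in the
#' high-score group); planted essential genes are strongly negative in all
#' lines. Per-line annotations carry the group label and ERBB2/PTEN status.
#'
#' @param n_genes Number of genes (background + planted).
#' @param n_lines Number of cell lines (>= 6 so each group can hold >= 3).
#' @param sl_spec Data frame with columns `gene`, `mean_high`, `mean_low`.
#' @param essential_spec Data frame with columns `gene`, `mean_all`
#'   (mean_all < -1 marks commonly essential genes).
#' @param noise_sd SD of the Gaussian noise on GE scores.
#' @param seed Integer seed.
#' @param n_high Number of lines in the high group (default: half, rounded
#'   up).
#' @return List with `screen` (a `ge_screen`: `values` gene x line matrix,
#'   `lines` annotation data frame, `essential` per-gene flag) and `truth`.
#' @export
generate_ge_screen <- function(n_genes, n_lines, sl_spec = NULL,
                               essential_spec = NULL, noise_sd = 0.1,
                               seed = 1L, n_high = ceiling(n_lines / 2)) {
  if (n_lines < 6) stop("n_lines must be >= 6 so both groups can have >= 3")
  if (!is.null(sl_spec) && !is.null(essential_spec) &&
      any(sl_spec$gene %in% essential_spec$gene))
    stop("a gene cannot appear in both sl_spec and essential_spec")
  genes <- sprintf("sg%04d", seq_len(n_genes))
  n_planted <- nrow(sl_spec %||% data.frame()) +
    nrow(essential_spec %||% data.frame())
  if (n_planted > n_genes) stop("more planted genes than n_genes")
  # planted specs claim the first gene ids unless they name existing ids
  if (!is.null(sl_spec) && !all(sl_spec$gene %in% genes))
    genes[seq_len(nrow(sl_spec))] <- sl_spec$gene
  if (!is.null(essential_spec) && !all(essential_spec$gene %in% genes)) {
    k <- nrow(sl_spec %||% data.frame())
    genes[k + seq_len(nrow(essential_spec))] <- essential_spec$gene
  }
  with_seed(seed, {
    lines <- sprintf("line%02d", seq_len(n_lines))
    high <- seq_len(n_lines) %in% sample(n_lines, n_high)
    mean_mat <- matrix(0, n_genes, n_lines, dimnames = list(genes, lines))
    if (!is.null(sl_spec))
      for (i in seq_len(nrow(sl_spec)))
        mean_mat[sl_spec$gene[i], ] <-
          ifelse(high, sl_spec$mean_high[i], sl_spec$mean_low[i])
    if (!is.null(essential_spec))
      for (i in seq_len(nrow(essential_spec)))
        mean_mat[essential_spec$gene[i], ] <- essential_spec$mean_all[i]
    values <- mean_mat + matrix(stats::rnorm(n_genes * n_lines, 0, noise_sd),
                                n_genes, n_lines)
    dimnames(values) <- dimnames(mean_mat)
    ann <- data.frame(
      line = lines,
      psilc_score = stats::rnorm(n_lines, ifelse(high, 1, -1), 0.2),
      psilc_group = ifelse(high, "high", "low"),
      erbb2_status = sample(c("amplified", "mutant", "wildtype"), n_lines,
                            replace = TRUE, prob = c(0.2, 0.1, 0.7)),
      pten_status = sample(c("mutant", "deleted", "wildtype"), n_lines,
                           replace = TRUE, prob = c(0.15, 0.1, 0.75)),
      stringsAsFactors = FALSE)
    screen <- ge_screen(values, ann)
    truth <- list(sl_genes = sl_spec$gene,
                  essential_genes = essential_spec$gene,
                  high_lines = lines[high], seed = seed)
    list(screen = screen, truth = truth)
  })
}

#' Construct a CRISPR gene-effect screen object
#'
#' @param values Gene x cell-line matrix of gene-effect scores (negative =
#'   loss of fitness on knockout).
#' @param lines Annotation data frame with columns `line`, `psilc_score`,
#'   `psilc_group`, `erbb2_status`, `pten_status`.
#' @return A `ge_screen` with per-gene `essential` flags (median GE across
#'   all lines < -1).
#' @export
ge_screen <- function(values, lines) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!all(colnames(values) == lines$line))
    stop("annotation rows must match matrix columns")
  essential <- apply(values, 1, stats::median) < -1
  structure(list(values = values, lines = lines, essential = essential),
            class = "ge_screen")
}

#' @export
print.ge_screen <- function(x, ...) {
  cat(sprintf("ge_screen: %d genes x %d lines (%d high / %d low), %d essential\n",
              nrow(x$values), ncol(x$values),
              sum(x$lines$psilc_group == "high"),
              sum(x$lines$psilc_group == "low"), sum(x$essential)))
  invisible(x)
}
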