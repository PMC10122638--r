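# Synthetic-data generators. Each generator emulates the statistical
# structure one analysis stage assumes (negative-binomial junction counts
# with library-size scaling, host-coupled linear counts, condition-biased
# cell clusters, laminar depth profiles) and returns the ground truth used
# by recovery tests. One RNG stream per call, seeded explicitly.

#' Parameters of the synthetic circRNA expression landscape
#'
#' Bundles the knobs of [gen_junction_counts()]: the number of circRNA
#' candidates, differentiation states and replicates, the fraction of
#' candidates with monotone up- (or down-) regulation across states, the
#' fraction whose linear host transcript scales with the circle, the
#' negative-binomial mean/dispersion, and the per-sample library-size range.
#'
#' Defaults mirror the design of a five-state neural differentiation
#' experiment profiled in biological triplicate with 417 high-abundance
#' circRNAs, most of which rise during differentiation.
#'
#' @param n_circ Number of circRNA candidates.
#' @param n_conditions Number of ordered cell states.
#' @param n_reps Replicates per state.
#' @param frac_up Fraction of candidates upregulated monotonically.
#' @param frac_down Fraction downregulated (small by default).
#' @param frac_host_coupled Fraction whose linear host counts scale with the
#'   circular counts; the rest keep state-independent linear counts.
#' @param base_mu Median expected BSJ count in state 1 at reference depth.
#' @param baseline_sdlog Log-normal spread (sdlog) of per-candidate baselines.
#' @param effect_log2fc Mean log2 fold change per state step for regulated
#'   candidates; 0 forces every candidate flat.
#' @param dispersion Negative-binomial dispersion (var = mu + dispersion*mu^2).
#' @param linear_factor Expected linear-to-circular count ratio.
#' @param libsize_range Length-2 numeric, min/max total reads per sample.
#' @param seed RNG seed.
#' @return An object of class `landscape_params` (a validated list).
#' @export
landscape_params <- function(n_circ = 417, n_conditions = 5, n_reps = 3,
                             frac_up = 0.6, frac_down = 0.03,
                             frac_host_coupled = 0.5,
                             base_mu = 20, baseline_sdlog = 0.8,
                             effect_log2fc = 1, dispersion = 0.2,
                             linear_factor = 2,
                             libsize_range = c(8e6, 1.2e7), seed = 1) {
  if (!is_count(n_circ) || !is_count(n_conditions) || n_conditions < 1 ||
      !is_count(n_reps) || n_reps < 1) {
    stop_circscape("n_circ, n_conditions, n_reps must be nonnegative counts (n_conditions, n_reps >= 1)",
                   "circscape_parameter_error")
  }
  check_fraction(frac_up, "frac_up")
  check_fraction(frac_down, "frac_down")
  check_fraction(frac_host_coupled, "frac_host_coupled")
  if (frac_up + frac_down > 1) {
    stop_circscape("frac_up + frac_down must not exceed 1", "circscape_parameter_error")
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop_circscape("dispersion must be > 0", "circscape_parameter_error")
  }
  if (!is.numeric(base_mu) || base_mu <= 0 || !is.numeric(linear_factor) ||
      linear_factor <= 0 || !is.numeric(baseline_sdlog) || baseline_sdlog < 0) {
    stop_circscape("base_mu and linear_factor must be > 0, baseline_sdlog >= 0",
                   "circscape_parameter_error")
  }
  if (!is.numeric(libsize_range) || length(libsize_range) != 2L ||
      any(libsize_range <= 0) || libsize_range[1] > libsize_range[2]) {
    stop_circscape("libsize_range must be positive with min <= max",
                   "circscape_parameter_error")
  }
  structure(list(
    n_circ = as.integer(n_circ), n_conditions = as.integer(n_conditions),
    n_reps = as.integer(n_reps), frac_up = frac_up, frac_down = frac_down,
    frac_host_coupled = frac_host_coupled, base_mu = base_mu,
    baseline_sdlog = baseline_sdlog, effect_log2fc = effect_log2fc,
    dispersion = dispersion, linear_factor = linear_factor,
    libsize_range = as.numeric(libsize_range), seed = seed
  ), class = "landscape_params")
}

#' Simulate BSJ and linear junction counts for a circRNA landscape
#'
#' Draws negative-binomial back-splice junction (BSJ) counts for `n_circ`
#' candidates over `n_conditions * n_reps` samples. Regulated candidates
#' change their expected count by `effect_log2fc` log2 units per state step;
#' expected counts are multiplied by each sample's library size relative to
#' the reference depth, so RPM normalization has variation to remove.
#' Host-coupled candidates get linear donor/acceptor counts proportional to
#' the circular mean (flat circular-to-linear ratio); host-independent
#' candidates keep state-constant linear means, so upregulated circles show
#' rising ratios.
#'
#' @param params A [landscape_params()] object.
#' @return A list with components `counts` (a [junction_count_set()]) and
#'   `truth` (data frame: id, class in up/down/flat, host_coupled, baseline
#'   mean, plus one `true_mean_<state>` column per state, at reference depth).
#' @examples
#' sim <- gen_junction_counts(landscape_params(n_circ = 20, seed = 7))
#' dim(sim$counts$bsj)
#' table(sim$truth$class)
#' @export
gen_junction_counts <- function(params) {
  if (!inherits(params, "landscape_params")) {
    stop_circscape("'params' must be created by landscape_params()",
                   "circscape_parameter_error")
  }
  p <- params
  set.seed(p$seed)
  n_samp <- p$n_conditions * p$n_reps
  conditions <- paste0("state", seq_len(p$n_conditions))
  samples <- data.frame(
    sample = paste0(rep(conditions, each = p$n_reps), "_rep",
                    rep(seq_len(p$n_reps), times = p$n_conditions)),
    condition = rep(conditions, each = p$n_reps),
    replicate = rep(seq_len(p$n_reps), times = p$n_conditions),
    library_size = round(stats::runif(n_samp, p$libsize_range[1], p$libsize_range[2])),
    stringsAsFactors = FALSE
  )

  # candidate labels
  n_up <- round(p$frac_up * p$n_circ)
  n_down <- round(p$frac_down * p$n_circ)
  cls <- rep("flat", p$n_circ)
  if (p$n_circ > 0 && p$effect_log2fc != 0) {
    cls[seq_len(n_up)] <- "up"
    if (n_down > 0) cls[n_up + seq_len(n_down)] <- "down"
  }
  cls <- if (p$n_circ > 0) sample(cls) else character(0)
  host_coupled <- if (p$n_circ > 0) {
    stats::runif(p$n_circ) < p$frac_host_coupled
  } else logical(0)

  baseline <- p$base_mu * stats::rlnorm(p$n_circ, 0, p$baseline_sdlog)
  dir <- ifelse(cls == "up", 1, ifelse(cls == "down", -1, 0))
  state_step <- outer(dir * p$effect_log2fc, seq_len(p$n_conditions) - 1)
  true_means <- baseline * 2^state_step            # n_circ x n_conditions
  lin_means <- if (p$n_circ > 0) {
    m <- true_means * p$linear_factor              # host-coupled profile
    m[!host_coupled, ] <- baseline[!host_coupled] * p$linear_factor
    m
  } else true_means

  ref_depth <- mean(p$libsize_range)
  depth_scale <- samples$library_size / ref_depth  # length n_samp
  size <- 1 / p$dispersion

  draw <- function(mean_by_state) {
    mu <- mean_by_state[, samples$condition_idx, drop = FALSE] *
      rep(depth_scale, each = nrow(mean_by_state))
    matrix(stats::rnbinom(length(mu), mu = mu, size = size),
           nrow = nrow(mean_by_state))
  }
  samples$condition_idx <- rep(seq_len(p$n_conditions), each = p$n_reps)

  bsj <- draw(true_means)
  donor <- draw(lin_means)
  acceptor <- draw(lin_means)
  samples$condition_idx <- NULL

  # invented genomic coordinates for candidate bookkeeping
  chrom <- paste0("chr", sample(1:22, p$n_circ, replace = TRUE))
  start <- sample.int(1e8, p$n_circ, replace = TRUE)
  end <- start + sample(200:20000, p$n_circ, replace = TRUE)
  strand <- sample(c("+", "-"), p$n_circ, replace = TRUE)
  candidates <- data.frame(
    chrom = chrom, start = start, end = end, strand = strand,
    id = sprintf("%s:%d-%d:%s", chrom, start, end, strand),
    stringsAsFactors = FALSE
  )

  dimn <- list(candidates$id, samples$sample)
  dimnames(bsj) <- dimnames(donor) <- dimnames(acceptor) <- dimn

  truth <- cbind(
    data.frame(id = candidates$id, class = cls, host_coupled = host_coupled,
               baseline = baseline, stringsAsFactors = FALSE),
    stats::setNames(as.data.frame(true_means),
                    paste0("true_mean_", conditions))
  )
  rownames(truth) <- NULL

  jcs <- junction_count_set(candidates, samples, bsj, donor, acceptor)
  list(counts = jcs, truth = truth)
}

#' Simulate a transcript set with an optional planted guide-binding site
#'
#' Generates uniform-random ACGT transcripts. When `planted_guide` is given,
#' its reverse complement (the sequence a guide strand would base-pair with)
#' is written into one transcript at a recorded position, so an off-target
#' scan has exactly one known perfect site to recover.
#'
#' @param n_transcripts Number of transcripts.
#' @param length Transcript length (nt).
#' @param planted_guide Optional guide sequence (ACGT/ACGU) to plant.
#' @param n_mismatches Mismatches to introduce into the planted site (0 =
#'   perfect complement).
#' @param seed RNG seed.
#' @return List with `records` (named character vector of sequences) and
#'   `planted` (NULL, or data frame with transcript, position, site sequence).
#' @export
gen_transcriptome <- function(n_transcripts, length, planted_guide = NULL,
                              n_mismatches = 0, seed = NULL) {
  if (!is_count(n_transcripts) || !is_count(length) || length < 1) {
    stop_circscape("n_transcripts and length must be counts (length >= 1)",
                   "circscape_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  if (n_transcripts == 0) return(list(records = character(0), planted = NULL))
  records <- vapply(seq_len(n_transcripts), function(i) {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  }, character(1))
  names(records) <- sprintf("NM_%06d", seq_len(n_transcripts))
  planted <- NULL
  if (!is.null(planted_guide)) {
    guide <- check_dna(rna_to_dna(planted_guide), "planted_guide")
    if (nchar(guide) > length) {
      stop_circscape("planted guide longer than transcripts",
                     "circscape_parameter_error")
    }
    site <- reverse_complement(guide)
    if (n_mismatches > 0) {
      pos_mm <- sample.int(nchar(site), n_mismatches)
      s <- strsplit(site, "")[[1]]
      for (k in pos_mm) s[k] <- sample(setdiff(c("A", "C", "G", "T"), s[k]), 1)
      site <- paste(s, collapse = "")
    }
    tx <- sample.int(n_transcripts, 1)
    pos <- sample.int(length - nchar(site) + 1L, 1)
    records[tx] <- paste0(
      substr(records[tx], 1, pos - 1L), site,
      substr(records[tx], pos + nchar(site), length)
    )
    planted <- data.frame(transcript = names(records)[tx], position = pos,
                          site = site, stringsAsFactors = FALSE)
  }
  list(records = records, planted = planted)
}

#' Simulate single cells across clusters with planted condition bias
#'
#' Each cell belongs to a cluster and a condition. In unbiased clusters the
#' condition is a fair coin; in planted biased clusters the cell derives
#' from the cluster's preferred condition with probability `bias_level`.
#' QC covariates (UMI, percent mitochondrial reads, gene counts) are drawn
#' so default QC filters retain the bulk of cells.
#'
#' @param n_clusters Number of clusters.
#' @param cells_per_cluster Cells per cluster.
#' @param biased_clusters Number of clusters with a planted condition bias.
#' @param bias_level Probability that a cell in a biased cluster comes from
#'   the preferred condition; must be in (0.5, 1].
#' @param conditions Two condition labels (control first).
#' @param seed RNG seed.
#' @return List with `cells` (data frame: cell_id, cluster, condition,
#'   umi_count, pct_mito, n_genes) and `truth` (data frame: cluster, biased,
#'   preferred condition or NA).
#' @export
gen_cluster_table <- function(n_clusters = 10, cells_per_cluster = 500,
                              biased_clusters = 3, bias_level = 0.9,
                              conditions = c("CTRL", "KD"), seed = NULL) {
  if (!is_count(n_clusters) || !is_count(cells_per_cluster) ||
      !is_count(biased_clusters) || biased_clusters > n_clusters) {
    stop_circscape("cluster counts must be valid nonnegative integers",
                   "circscape_parameter_error")
  }
  if (!is.numeric(bias_level) || bias_level <= 0.5 || bias_level > 1) {
    stop_circscape("bias_level must lie in (0.5, 1]", "circscape_parameter_error")
  }
  if (length(conditions) != 2L) {
    stop_circscape("exactly two condition labels are required",
                   "circscape_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  cluster_ids <- paste0("cluster", seq_len(n_clusters))
  biased <- rep(FALSE, n_clusters)
  biased[sample.int(n_clusters, biased_clusters)] <- TRUE
  preferred <- ifelse(biased, sample(conditions, n_clusters, replace = TRUE), NA)

  cells_list <- lapply(seq_len(n_clusters), function(k) {
    p_pref <- if (biased[k]) bias_level else 0.5
    toward <- if (biased[k]) preferred[k] else conditions[1]
    other <- setdiff(conditions, toward)
    cond <- ifelse(stats::runif(cells_per_cluster) < p_pref, toward, other)
    data.frame(
      cell_id = sprintf("%s_cell%04d", cluster_ids[k], seq_len(cells_per_cluster)),
      cluster = cluster_ids[k],
      condition = cond,
      umi_count = round(stats::rlnorm(cells_per_cluster, log(1500), 0.6)),
      pct_mito = pmin(100, stats::rexp(cells_per_cluster, rate = 1 / 2)),
      n_genes = round(stats::rlnorm(cells_per_cluster, log(800), 0.5)),
      stringsAsFactors = FALSE
    )
  })
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  truth <- data.frame(cluster = cluster_ids, biased = biased,
                      preferred = preferred, stringsAsFactors = FALSE)
  list(cells = cells, truth = truth)
}

#' Simulate a laminar depth-intensity profile with known subregion mass
#'
#' Builds a signal profile along normalized cortical depth (0 = ventricular
#' surface, 1 = pial surface) whose noiseless mass in the upper-layer (UL),
#' deep-layer (DL, the Ctip2-positive interval) and ventricular-zone (VZ)
#' subregions equals the requested fractions exactly, so the migration
#' quantification can be validated by round trip.
#'
#' @param n_points Number of evaluation points (cell midpoints on \[0, 1\]).
#' @param ul_frac,dl_frac,vz_frac Subregion mass fractions; must sum to 1.
#' @param ctip2_interval Length-2 numeric in \[0, 1\], the Ctip2-positive
#'   (deep-layer) depth interval.
#' @param noise_sd Standard deviation of additive Gaussian noise (intensity
#'   truncated at zero).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return A [depth_profile()] object with the requested Ctip2 interval.
#' @export
gen_depth_profile <- function(n_points = 1000, ul_frac, dl_frac, vz_frac,
                              ctip2_interval = c(0.25, 0.55),
                              noise_sd = 0, seed = NULL) {
  fr <- c(vz = vz_frac, dl = dl_frac, ul = ul_frac)
  if (!is.numeric(fr) || any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    stop_circscape("ul_frac, dl_frac, vz_frac must be nonnegative and sum to 1",
                   "circscape_parameter_error")
  }
  if (!is.numeric(ctip2_interval) || length(ctip2_interval) != 2L ||
      ctip2_interval[1] >= ctip2_interval[2] ||
      ctip2_interval[1] < 0 || ctip2_interval[2] > 1) {
    stop_circscape("ctip2_interval must be an increasing interval within [0, 1]",
                   "circscape_parameter_error")
  }
  if (!is_count(n_points) || n_points < 3) {
    stop_circscape("n_points must be an integer >= 3", "circscape_parameter_error")
  }
  positions <- (seq_len(n_points) - 0.5) / n_points
  lo <- ctip2_interval[1]; hi <- ctip2_interval[2]
  region <- ifelse(positions < lo, "vz", ifelse(positions <= hi, "dl", "ul"))
  n_reg <- table(factor(region, levels = c("vz", "dl", "ul")))
  for (r in names(fr)) {
    if (fr[[r]] > 0 && n_reg[[r]] == 0) {
      stop_circscape(sprintf("no evaluation points fall in subregion '%s'; increase n_points", r),
                     "circscape_parameter_error")
    }
  }
  intensity <- numeric(n_points)
  for (r in names(fr)) {
    if (n_reg[[r]] > 0) intensity[region == r] <- fr[[r]] / n_reg[[r]]
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    intensity <- pmax(0, intensity + stats::rnorm(n_points, 0, noise_sd))
  }
  depth_profile(positions, intensity, ctip2_interval)
}
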