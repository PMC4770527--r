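#' Configuration for the synthetic cohort generator
#'
#' Builds and validates the parameter set for [generate_cohort()]. The
#' defaults describe the cohort structure the analysis pipeline assumes: a
#' tumor cohort partitioned into methylation epitypes, a normal cohort with
#' near-constitutive methylation states, bimodal beta values with
#' assay-type-II peak compression, planted tumor-specific CpG classes with
#' graded epitype patterns, methylation--expression coupling, detection-p
#' censoring, copy-number and mutation structure, and epitype-dependent
#' survival.
#'
#' Epitype roles are positional: epitype 1 is normal-like (no planted
#' deviations), the last epitype is basal-like, the third-from-last is the
#' hypermethylated luminal epitype, the fourth-from-last is the globally
#' hypomethylated epitype, and the second-from-last carries the
#' amplification-rich phenotype. With the default `n_epitypes = 7` this gives
#' the conventional ET1/ET4/ET5/ET6/ET7 layout.
#'
#' @param n_tumors,n_normals,n_probes cohort and platform sizes.
#' @param n_epitypes number of planted tumor epitypes (>= 2; pattern classes
#'   require >= 5).
#' @param epitype_proportions simplex weights over epitypes (sum to 1);
#'   default equal.
#' @param unmeth_peak,meth_peak beta locations of the unmethylated and
#'   methylated peaks for type-I probes.
#' @param noise_sd beta-scale standard deviation of measurement noise
#'   (truncated-normal around the planted mean).
#' @param typeII_compression length-2 non-negative shifts `(up, down)`: the
#'   type-II unmethylated peak sits at `unmeth_peak + up` and the methylated
#'   peak at `meth_peak - down` (dynamic-range compression toward 0.5).
#' @param frac_typeII fraction of probes on the type-II chemistry.
#' @param frac_cancer_meth_sites,frac_cancer_unmeth_sites fractions of probes
#'   planted as generically tumor-methylated / tumor-demethylated (switching
#'   in a random subset of tumors).
#' @param pattern_sites named integer vector of planted epitype-pattern set
#'   sizes: `basal_meth` (methylated in the basal-like and hypermethylated
#'   luminal epitypes), `luminal_meth` (methylated specifically along the
#'   luminal gradient), `global_hypo` (demethylated specifically in the
#'   globally hypomethylated epitype), `luminal_hypo` (demethylated across
#'   luminal epitypes), `basal_hypo` (demethylated specifically in the
#'   basal-like epitype).
#' @param marker_sites number of private methylation marker CpGs planted for
#'   each epitype without a pattern-class signature (all epitypes except the
#'   normal-like, basal-like, hypermethylated-luminal and global-hypo ones).
#' @param gradient_spec optional class-by-group matrix of mean beta targets
#'   overriding the built-in gradient (rows = site classes, columns =
#'   `"normal"` plus epitype labels); `NULL` uses [default_gradient()].
#' @param switch_fraction_range range of per-probe tumor fractions switching
#'   status at generically tumor-specific sites.
#' @param expr_coupling named slopes linking expression to planted beta for
#'   the pattern classes (0 = uncoupled).
#' @param expr_noise_sd residual sd of coupled expression values.
#' @param n_filler_genes uncoupled background genes in the expression matrix.
#' @param missing_rate probability a probe/sample measurement is censored
#'   (detection p or bead count failure).
#' @param n_cn_probes copy-number platform size.
#' @param survival_rates per-epitype exponential event rates (per year);
#'   default a gradient increasing away from the normal-like epitype.
#' @param censor_max_years upper bound of the uniform censoring time.
#' @param seed RNG seed (Mersenne-Twister); identical seeds give identical
#'   cohorts.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumors = 120L, n_normals = 96L, n_probes = 5000L,
                          n_epitypes = 7L,
                          epitype_proportions = NULL,
                          unmeth_peak = 0.05, meth_peak = 0.95,
                          noise_sd = 0.05,
                          typeII_compression = c(0.05, 0.07),
                          frac_typeII = 0.72,
                          frac_cancer_meth_sites = 0.05,
                          frac_cancer_unmeth_sites = 0.05,
                          pattern_sites = c(basal_meth = 39L, luminal_meth = 90L,
                                            global_hypo = 110L, luminal_hypo = 130L,
                                            basal_hypo = 40L),
                          marker_sites = 40L,
                          gradient_spec = NULL,
                          switch_fraction_range = c(0.06, 0.15),
                          expr_coupling = c(luminal_meth = -1, global_hypo = 1,
                                            luminal_hypo = 1, basal_meth = 0,
                                            basal_hypo = 0),
                          expr_noise_sd = 0.3,
                          n_filler_genes = 300L,
                          missing_rate = 0.005,
                          n_cn_probes = 2000L,
                          survival_rates = NULL,
                          censor_max_years = 25,
                          seed = 1L) {
  n_epitypes <- as.integer(n_epitypes)
  if (n_epitypes < 2L) stop("n_epitypes must be >= 2")
  if (is.null(epitype_proportions))
    epitype_proportions <- rep(1 / n_epitypes, n_epitypes)
  if (length(epitype_proportions) != n_epitypes)
    stop("epitype_proportions must have length n_epitypes")
  if (abs(sum(epitype_proportions) - 1) > 1e-9)
    stop("epitype_proportions must sum to 1")
  stop_if_not_scalar_number(unmeth_peak, "unmeth_peak", 0, 1)
  stop_if_not_scalar_number(meth_peak, "meth_peak", 0, 1)
  if (meth_peak <= unmeth_peak)
    stop("meth_peak must be greater than unmeth_peak")
  stop_if_not_scalar_number(noise_sd, "noise_sd", 0, 0.5)
  stop_if_not_scalar_number(missing_rate, "missing_rate", 0, 1)
  if (length(typeII_compression) != 2L || any(typeII_compression < 0))
    stop("typeII_compression must be two non-negative peak shifts")
  if (is.null(survival_rates)) {
    ## hazards follow the epitype roles: intermediate for the normal-like
    ## epitype, rising along the luminal gradient, highest for the
    ## amplification-rich epitype, high for the basal-like one
    survival_rates <- if (n_epitypes >= 5)
      c(0.04, seq(0.015, 0.09, length.out = n_epitypes - 3), 0.10, 0.07)
    else seq(0.02, 0.09, length.out = n_epitypes)
  }
  if (length(survival_rates) != n_epitypes)
    stop("survival_rates must have length n_epitypes")
  required_patterns <- c("basal_meth", "luminal_meth", "global_hypo",
                         "luminal_hypo", "basal_hypo")
  if (!all(required_patterns %in% names(pattern_sites)))
    stop("pattern_sites must name: ", paste(required_patterns, collapse = ", "))
  cfg <- list(n_tumors = as.integer(n_tumors), n_normals = as.integer(n_normals),
              n_probes = as.integer(n_probes), n_epitypes = n_epitypes,
              epitype_proportions = epitype_proportions,
              unmeth_peak = unmeth_peak, meth_peak = meth_peak,
              noise_sd = noise_sd, typeII_compression = typeII_compression,
              frac_typeII = frac_typeII,
              frac_cancer_meth_sites = frac_cancer_meth_sites,
              frac_cancer_unmeth_sites = frac_cancer_unmeth_sites,
              pattern_sites = pattern_sites, marker_sites = as.integer(marker_sites),
              gradient_spec = gradient_spec,
              switch_fraction_range = switch_fraction_range,
              expr_coupling = expr_coupling, expr_noise_sd = expr_noise_sd,
              n_filler_genes = as.integer(n_filler_genes),
              missing_rate = missing_rate, n_cn_probes = as.integer(n_cn_probes),
              survival_rates = survival_rates,
              censor_max_years = censor_max_years, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

## Role indices of the planted epitypes (positional convention, see
## ?cohort_config). Returns NA roles when n_epitypes < 5.
epitype_roles <- function(k) {
  if (k < 5L)
    return(list(normal_like = 1L, basal = NA_integer_, hyper_luminal = NA_integer_,
                global_hypo = NA_integer_, amp_rich = NA_integer_,
                marker = setdiff(seq_len(k), 1L)))
  list(normal_like = 1L,
       basal = k,
       hyper_luminal = k - 2L,
       global_hypo = k - 3L,
       amp_rich = k - 1L,
       marker = setdiff(seq_len(k), c(1L, k, k - 2L, k - 3L)))
}

#' Default per-epitype mean beta targets for planted site classes
#'
#' Builds the class-by-group matrix of noise-free mean beta values used by
#' [generate_cohort()]: columns are `"normal"` followed by the epitype
#' labels, rows are the planted site classes. The luminal classes carry a
#' graded pattern (gradual hypermethylation toward the hypermethylated
#' luminal epitype, gradual demethylation toward it for the luminal-hypo
#' class), the basal-like class mirrors methylation shared with the
#' hypermethylated luminal epitype, and the globally hypomethylated and
#' basal-like hypo classes are private to their epitype.
#'
#' @param n_epitypes number of epitypes (>= 5 for pattern classes).
#' @param unmeth_peak,meth_peak peak locations, as in [cohort_config()].
#' @return numeric matrix with rownames the site classes and colnames
#'   `c("normal", "ET1", ..., "ETk")`.
#' @export
default_gradient <- function(n_epitypes = 7L, unmeth_peak = 0.05,
                             meth_peak = 0.95) {
  k <- as.integer(n_epitypes)
  u <- unmeth_peak; m <- meth_peak
  roles <- epitype_roles(k)
  ets <- paste0("ET", seq_len(k))
  classes <- c("const_unmeth", "const_meth", "basal_meth", "luminal_meth",
               "global_hypo", "luminal_hypo", "basal_hypo",
               paste0("marker_ET", roles$marker))
  g <- matrix(NA_real_, nrow = length(classes), ncol = k + 1L,
              dimnames = list(classes, c("normal", ets)))
  g["const_unmeth", ] <- u
  g["const_meth", ] <- m
  for (mk in roles$marker) {
    g[paste0("marker_ET", mk), ] <- u
    g[paste0("marker_ET", mk), ets[mk]] <- m
  }
  if (k >= 5L) {
    lum_path <- seq(2L, roles$hyper_luminal - 1L)   # graded luminal epitypes
    ## methylated in the basal-like epitype, shared with hypermethylated
    ## luminal tumors; graded low-level gain along the luminal path
    g["basal_meth", ] <- u
    g["basal_meth", ets[lum_path]] <- seq(u + 0.05, 0.35, length.out = length(lum_path))
    g["basal_meth", ets[roles$hyper_luminal]] <- m
    g["basal_meth", ets[roles$basal]] <- m
    ## methylated specifically along the luminal gradient, absent in basal
    g["luminal_meth", ] <- u
    g["luminal_meth", ets[lum_path]] <- seq(u + 0.1, 0.4, length.out = length(lum_path))
    g["luminal_meth", ets[roles$hyper_luminal]] <- m
    ## demethylated only in the globally hypomethylated epitype
    g["global_hypo", ] <- m
    g["global_hypo", ets[roles$global_hypo]] <- u
    ## gradual demethylation across luminal epitypes, strongest in the
    ## hypermethylated luminal epitype; basal stays methylated
    g["luminal_hypo", ] <- m
    g["luminal_hypo", ets[lum_path]] <- seq(0.8, 0.3, length.out = length(lum_path))
    g["luminal_hypo", ets[roles$global_hypo]] <- 0.25
    g["luminal_hypo", ets[roles$hyper_luminal]] <- u
    ## demethylated only in the basal-like epitype
    g["basal_hypo", ] <- m
    g["basal_hypo", ets[roles$basal]] <- u
  }
  g
}

## Integer allocation of n samples to epitypes by largest remainder.
allocate_counts <- function(n, prop) {
  raw <- prop * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    idx <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[idx] <- cnt[idx] + 1
  }
  as.integer(cnt)
}

#' Generate a synthetic methylation cohort with planted ground truth
#'
#' Draws a full multi-platform cohort under the structure described in
#' [cohort_config()]: probe-level signal intensities, a beta matrix (tumors
#' and normals), probe annotation, a relative (mean-centered log2) expression
#' matrix with planted methylation--expression coupling, probe-level copy
#' number with planted amplifications, a multi-experiment mutation table,
#' a clinical table with epitype-dependent survival, and the planted truth
#' needed for recovery tests.
#'
#' Beta values are drawn from truncated normal distributions centered on the
#' planted per-class, per-epitype means; type-II probes have their means
#' linearly compressed toward 0.5 (peaks at `unmeth_peak + up` and
#' `meth_peak - down`), reproducing the assay dialect that peak
#' normalization must remove. Two planted promoter-driver genes mimic
#' candidate drivers regulated by promoter methylation: `PRM1L` (silenced by
#' promoter hypermethylation in a subset of basal-like tumors, as for BRCA1)
#' and `PRM2L` (constitutively methylated, demethylated and expressed in a
#' subset of basal-like tumors, as for HORMAD1).
#'
#' @param config a [cohort_config()].
#' @return A list of class `methylation_cohort` with elements `signals`,
#'   `beta` (a [beta_matrix()] over tumors then normals), `annotation`,
#'   `expression` (genes x tumors, relative mode), `transcripts`,
#'   `copynumber`, `mutations`, `clinical`, `sample_info`, `chrom_lengths`
#'   and `truth`.
#' @examples
#' cfg <- cohort_config(n_tumors = 30, n_normals = 12, n_probes = 400,
#'                      seed = 7)
#' cohort <- generate_cohort(cfg)
#' table(cohort$truth$epitype_labels)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed, kind = "Mersenne-Twister")
  k <- config$n_epitypes
  roles <- epitype_roles(k)
  ets <- paste0("ET", seq_len(k))
  u <- config$unmeth_peak; m <- config$meth_peak
  nT <- config$n_tumors; nN <- config$n_normals; nP <- config$n_probes

  tumor_ids <- if (nT > 0) sprintf("T%04d", seq_len(nT)) else character(0)
  normal_ids <- if (nN > 0) sprintf("N%04d", seq_len(nN)) else character(0)
  probe_ids <- sprintf("cg%08d", seq_len(nP))

  ## ---- epitype labels ------------------------------------------------
  counts <- allocate_counts(nT, config$epitype_proportions)
  labels <- sample(rep(ets, counts))
  names(labels) <- tumor_ids
  by_epitype <- split(tumor_ids, factor(labels, levels = ets))

  ## ---- site classes --------------------------------------------------
  gradient <- config$gradient_spec %||%
    default_gradient(k, u, m)
  have_patterns <- k >= 5L && nT > 0
  n_generic_meth <- if (nT > 0) round(config$frac_cancer_meth_sites * nP) else 0L
  n_generic_unmeth <- if (nT > 0) round(config$frac_cancer_unmeth_sites * nP) else 0L
  ps <- config$pattern_sites
  class_counts <- c(
    if (have_patterns) c(basal_meth = unname(ps["basal_meth"]),
                         luminal_meth = unname(ps["luminal_meth"]),
                         global_hypo = unname(ps["global_hypo"]),
                         luminal_hypo = unname(ps["luminal_hypo"]),
                         basal_hypo = unname(ps["basal_hypo"])),
    if (nT > 0) stats::setNames(rep(config$marker_sites, length(roles$marker)),
                                paste0("marker_ET", roles$marker)),
    cancer_meth = n_generic_meth, cancer_unmeth = n_generic_unmeth)
  n_special <- sum(class_counts) + 21L  # + promoter-driver CpGs
  if (n_special > nP)
    stop("n_probes too small for the planted site classes")
  n_const <- nP - n_special
  n_const_unmeth <- round(0.6 * n_const)
  site_class <- c(rep(names(class_counts), class_counts),
                  rep("prm1_informative", 8L), rep("prm1_flat", 4L),
                  rep("prm2_informative", 7L), rep("prm2_flat", 2L),
                  rep("const_unmeth", n_const_unmeth),
                  rep("const_meth", n_const - n_const_unmeth))
  site_class <- sample(site_class)           # shuffle classes over probe ids
  names(site_class) <- probe_ids

  ## ---- planted mean matrix (probes x samples, noise-free) -----------
  mu <- matrix(NA_real_, nrow = nP, ncol = nT + nN,
               dimnames = list(probe_ids, c(tumor_ids, normal_ids)))
  grp_of_sample <- c(labels[tumor_ids], stats::setNames(rep("normal", nN), normal_ids))
  for (cl in rownames(gradient)) {
    idx <- which(site_class == cl)
    if (!length(idx)) next
    mu[idx, ] <- matrix(gradient[cl, grp_of_sample[colnames(mu)]],
                        nrow = length(idx), ncol = ncol(mu), byrow = TRUE)
  }
  ## generic tumor-specific sites: switch a stratified random tumor subset
  switch_sets <- list()
  plant_generic <- function(cls, from, to) {
    idx <- which(site_class == cls)
    for (i in idx) {
      mu[i, ] <<- from
      if (nT > 0) {
        f <- stats::runif(1, config$switch_fraction_range[1],
                          config$switch_fraction_range[2])
        sw <- unlist(lapply(by_epitype, function(s) {
          ns <- max(if (length(s)) 1L else 0L, round(f * length(s)))
          if (ns > 0) sample(s, min(ns, length(s))) else character(0)
        }), use.names = FALSE)
        mu[i, sw] <<- to
        switch_sets[[probe_ids[i]]] <<- sw
      }
    }
  }
  plant_generic("cancer_meth", u, m)
  plant_generic("cancer_unmeth", m, u)

  ## promoter-driver genes: PRM1L (hypermethylated-silenced subset of the
  ## basal-like epitype) and PRM2L (demethylated-expressed subset)
  basal_label <- if (!is.na(roles$basal)) ets[roles$basal] else ets[k]
  basal_samples <- tumor_ids[labels == basal_label]
  prm1_silenced <- if (length(basal_samples))
    sample(basal_samples, ceiling(0.5 * length(basal_samples))) else character(0)
  prm2_unmeth <- if (length(basal_samples))
    sample(basal_samples, ceiling(0.7 * length(basal_samples))) else character(0)
  i1 <- which(site_class == "prm1_informative")
  mu[i1, ] <- u / 2                       # active promoter, low beta
  mu[i1, prm1_silenced] <- 0.6            # silenced subset
  mu[which(site_class == "prm1_flat"), ] <- u / 2
  i2 <- which(site_class == "prm2_informative")
  mu[i2, ] <- m                           # constitutively methylated promoter
  mu[i2, prm2_unmeth] <- u                # demethylated (expressed) subset
  mu[which(site_class == "prm2_flat"), ] <- m

  ## ---- assay chemistry and type-II compression ----------------------
  assay <- sample(c("I", "II"), nP, replace = TRUE,
                  prob = c(1 - config$frac_typeII, config$frac_typeII))
  u2 <- u + config$typeII_compression[1]
  m2 <- m - config$typeII_compression[2]
  muc <- mu
  ii <- assay == "II"
  muc[ii, ] <- u2 + (mu[ii, , drop = FALSE] - u) * (m2 - u2) / (m - u)

  ## ---- observed beta: truncated-normal noise + censoring -------------
  beta <- matrix(rtrunc01(length(muc), as.vector(muc), config$noise_sd),
                 nrow = nP, dimnames = dimnames(muc))
  censored <- matrix(stats::runif(length(beta)) < config$missing_rate,
                     nrow = nP, dimnames = dimnames(beta))

  ## ---- signal table ---------------------------------------------------
  total <- matrix(stats::rlnorm(length(beta), log(4000), 0.3), nrow = nP)
  det_p <- matrix(stats::runif(length(beta), 0, 0.01), nrow = nP)
  beads <- matrix(stats::rpois(length(beta), 14) + 3L, nrow = nP)
  ## censored cells fail either the detection-p or the bead-count rule
  if (any(censored)) {
    ic <- which(censored)
    fail_p <- stats::runif(length(ic)) < 0.5
    det_p[ic[fail_p]] <- stats::runif(sum(fail_p), 0.06, 0.5)
    beads[ic[!fail_p]] <- sample(1:2, sum(!fail_p), replace = TRUE)
  }
  signals <- data.frame(
    probe_id = rep(probe_ids, times = ncol(beta)),
    sample_id = rep(colnames(beta), each = nP),
    M = as.vector(beta * total),
    U = as.vector((1 - beta) * total),
    detection_p = as.vector(det_p),
    n_beads = as.vector(beads),
    stringsAsFactors = FALSE)
  beta[censored] <- NA_real_

  ## ---- probe annotation ----------------------------------------------
  chrom_lengths <- stats::setNames(round(seq(240e6, 45e6, length.out = 22)),
                                   paste0("chr", 1:22))
  chrom <- sample(names(chrom_lengths), nP, replace = TRUE)
  pos <- floor(stats::runif(nP, 1, chrom_lengths[chrom])) + 1
  ## globally hypomethylated sites are planted subtelomeric (within 5 Mb of
  ## a chromosome end)
  ig <- which(site_class == "global_hypo")
  if (length(ig)) {
    d <- floor(stats::runif(length(ig), 0, 5e6))
    at_start <- stats::runif(length(ig)) < 0.5
    pos[ig] <- ifelse(at_start, d + 1, chrom_lengths[chrom[ig]] - d)
  }
  region <- rep("Body", nP)
  island <- rep("OpenSea", nP)
  promoter_classes <- c("luminal_meth", "basal_meth",
                        paste0("marker_ET", roles$marker))
  ip <- site_class %in% promoter_classes
  region[ip] <- sample(c("TSS200", "TSS1500"), sum(ip), replace = TRUE)
  island[ip] <- "Island"
  icu <- which(site_class == "const_unmeth")
  ipu <- icu[seq_len(round(0.6 * length(icu)))]
  region[ipu] <- sample(c("TSS200", "TSS1500"), length(ipu), replace = TRUE)
  island[ipu] <- "Island"
  ih <- site_class %in% c("luminal_hypo", "basal_hypo", "cancer_unmeth")
  island[ih] <- sample(c("OpenSea", "Shore"), sum(ih), replace = TRUE,
                       prob = c(0.8, 0.2))

  ## gene mapping: coupled pattern classes get one unique gene per probe
  gene <- rep(NA_character_, nP)
  coupled_classes <- names(config$expr_coupling)
  ic <- which(site_class %in% coupled_classes)
  gene[ic] <- sprintf("GM%05d", seq_along(ic))
  ## a few probes map ambiguously to two genes (excluded downstream)
  iamb <- which(site_class == "const_meth")[seq_len(min(10L, sum(site_class == "const_meth")))]
  gene[iamb] <- "AMBA;AMBB"
  gene[grepl("^prm1", site_class)] <- "PRM1L"
  gene[grepl("^prm2", site_class)] <- "PRM2L"

  ## promoter-driver transcripts; informative CpGs within 1 kb of the TSS,
  ## flat CpGs in the transcript body
  transcripts <- data.frame(
    gene = c("PRM1L", "PRM2L"),
    chrom = c("chr17", "chr1"),
    start = c(41.19e6, 150.4e6),
    end = c(41.28e6, 150.46e6),
    strand = c("-", "+"),
    stringsAsFactors = FALSE)
  tss <- ifelse(transcripts$strand == "+", transcripts$start, transcripts$end)
  names(tss) <- transcripts$gene
  place_promoter <- function(cls, gene_name, informative) {
    idx <- which(site_class == cls)
    chrom[idx] <<- transcripts$chrom[transcripts$gene == gene_name]
    if (informative) {
      pos[idx] <<- round(tss[gene_name] + stats::runif(length(idx), -500, 500))
    } else {
      tr <- transcripts[transcripts$gene == gene_name, ]
      pos[idx] <<- round(stats::runif(length(idx), tr$start + 2000, tr$end - 2000))
    }
    region[idx] <<- if (informative) "TSS200" else "Body"
    island[idx] <<- if (informative) "Island" else "OpenSea"
  }
  place_promoter("prm1_informative", "PRM1L", TRUE)
  place_promoter("prm1_flat", "PRM1L", FALSE)
  place_promoter("prm2_informative", "PRM2L", TRUE)
  place_promoter("prm2_flat", "PRM2L", FALSE)

  annotation <- data.frame(probe_id = probe_ids, chrom = chrom, pos = pos,
                           assay_type = assay, gene = gene, region = region,
                           island = island, stringsAsFactors = FALSE)

  ## ---- expression (relative mode: mean-centered log-scale values) -----
  expr_rows <- list()
  if (nT > 0) {
    for (cl in coupled_classes) {
      idx <- which(site_class == cl)
      if (!length(idx)) next
      slope <- config$expr_coupling[[cl]]
      em <- 2 + slope * 3 * mu[idx, tumor_ids, drop = FALSE] +
        matrix(stats::rnorm(length(idx) * nT, 0, config$expr_noise_sd),
               nrow = length(idx))
      rownames(em) <- gene[idx]
      expr_rows[[cl]] <- em
    }
    e1 <- 4 - 5 * colMeans(mu[i1, tumor_ids, drop = FALSE]) +
      stats::rnorm(nT, 0, config$expr_noise_sd)
    e2 <- 4 - 4 * colMeans(mu[i2, tumor_ids, drop = FALSE]) +
      stats::rnorm(nT, 0, config$expr_noise_sd)
    expr_rows$promoter <- rbind(PRM1L = e1, PRM2L = e2)
    if (config$n_filler_genes > 0) {
      fill <- matrix(stats::rnorm(config$n_filler_genes * nT, 0, 1),
                     nrow = config$n_filler_genes,
                     dimnames = list(sprintf("BG%05d", seq_len(config$n_filler_genes)),
                                     tumor_ids))
      expr_rows$filler <- fill
    }
  }
  expression <- if (length(expr_rows)) do.call(rbind, expr_rows) else
    matrix(numeric(0), nrow = 0, ncol = nT, dimnames = list(NULL, tumor_ids))
  colnames(expression) <- tumor_ids
  expression <- expression - rowMeans(expression)   # relative mode
  attr(expression, "mode") <- "relative"

  ## ---- copy number -----------------------------------------------------
  cn_chrom <- sample(names(chrom_lengths), config$n_cn_probes, replace = TRUE)
  cn_pos <- floor(stats::runif(config$n_cn_probes, 1, chrom_lengths[cn_chrom])) + 1
  ord <- order(match(cn_chrom, names(chrom_lengths)), cn_pos)
  cn_probes <- data.frame(probe_id = sprintf("cn%06d", seq_len(config$n_cn_probes)),
                          chrom = cn_chrom[ord], pos = cn_pos[ord],
                          stringsAsFactors = FALSE)
  ## five recurrent amplification regions of ~15 probes each
  regions <- do.call(rbind, lapply(1:5, function(r) {
    ch <- paste0("chr", c(17, 8, 11, 20, 1)[r])
    on_ch <- which(cn_probes$chrom == ch)
    w <- min(15L, length(on_ch))
    if (w < 3L) return(NULL)
    i0 <- sample(seq_len(length(on_ch) - w + 1L), 1)
    span <- on_ch[i0:(i0 + w - 1L)]
    data.frame(region = sprintf("AMP%d", r), chrom = ch,
               start = cn_probes$pos[span[1]], end = cn_probes$pos[span[w]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(regions))
    regions <- data.frame(region = character(0), chrom = character(0),
                          start = numeric(0), end = numeric(0),
                          stringsAsFactors = FALSE)
  fga_target <- seq(0.05, 0.35, length.out = k)
  estimate <- matrix(stats::rnorm(config$n_cn_probes * nT, 0, 0.05),
                     nrow = config$n_cn_probes,
                     dimnames = list(cn_probes$probe_id, tumor_ids))
  call <- matrix("neutral", nrow = config$n_cn_probes, ncol = nT,
                 dimnames = dimnames(estimate))
  amp_truth <- matrix(FALSE, nrow = nrow(regions), ncol = nT,
                      dimnames = list(regions$region, tumor_ids))
  amp_label <- if (!is.na(roles$amp_rich)) ets[roles$amp_rich] else NA_character_
  for (j in seq_len(nT)) {
    f <- fga_target[match(labels[j], ets)]
    alt <- sample(config$n_cn_probes, round(f * config$n_cn_probes))
    gain <- alt[seq_len(floor(length(alt) / 2))]
    loss <- setdiff(alt, gain)
    estimate[gain, j] <- stats::rnorm(length(gain), 0.6, 0.1)
    estimate[loss, j] <- stats::rnorm(length(loss), -0.6, 0.1)
    call[gain, j] <- "gain"; call[loss, j] <- "loss"
    p_amp <- if (!is.na(amp_label) && labels[j] == amp_label) 0.7 else 0.05
    for (r in seq_len(nrow(regions))) {
      if (stats::runif(1) < p_amp) {
        in_r <- cn_probes$chrom == regions$chrom[r] &
          cn_probes$pos >= regions$start[r] & cn_probes$pos <= regions$end[r]
        estimate[in_r, j] <- stats::rnorm(sum(in_r), 1.5, 0.1)
        call[in_r, j] <- "gain"
        amp_truth[r, j] <- TRUE
      }
    }
  }
  copynumber <- list(probes = cn_probes, estimate = estimate, call = call,
                     regions = regions)

  ## ---- mutations -------------------------------------------------------
  mut_genes <- list(
    PIK3CA = ifelse(match(labels, ets) %in% setdiff(2:max(2, k - 2), NA), 0.35, 0.08),
    TP53 = ifelse(match(labels, ets) >= max(2, k - 2), 0.5, 0.1),
    CDH1 = ifelse(match(labels, ets) %in% c(2, 3), 0.25, 0.03))
  maf_rows <- list()
  second_exp <- if (nT > 0) sample(tumor_ids, round(0.15 * nT)) else character(0)
  for (g in names(mut_genes)) {
    hit <- tumor_ids[stats::runif(nT) < mut_genes[[g]]]
    for (s in hit) maf_rows[[length(maf_rows) + 1L]] <-
      data.frame(Hugo_Symbol = g, Tumor_Sample_Barcode = s,
                 Variant_Classification = sample(c("Missense_Mutation",
                                                   "Nonsense_Mutation"), 1),
                 stringsAsFactors = FALSE)
  }
  bg_genes <- sprintf("MG%03d", 1:30)
  for (g in bg_genes) {
    hit <- tumor_ids[stats::runif(nT) < 0.02]
    for (s in hit) maf_rows[[length(maf_rows) + 1L]] <-
      data.frame(Hugo_Symbol = g, Tumor_Sample_Barcode = s,
                 Variant_Classification = sample(c("Missense_Mutation", "Silent"),
                                                 1, prob = c(0.8, 0.2)),
                 stringsAsFactors = FALSE)
  }
  maf <- if (length(maf_rows)) do.call(rbind, maf_rows) else
    data.frame(Hugo_Symbol = character(0), Tumor_Sample_Barcode = character(0),
               Variant_Classification = character(0), stringsAsFactors = FALSE)
  ## experiment structure: every tumor has E1; a subset also has E2, in
  ## which each call is independently re-detected with probability 0.9
  maf$Experiment <- rep("E1", nrow(maf))
  if (nrow(maf) > 0 && length(second_exp)) {
    dup <- maf[maf$Tumor_Sample_Barcode %in% second_exp, , drop = FALSE]
    if (nrow(dup)) {
      keep <- stats::runif(nrow(dup)) < 0.9
      dup <- dup[keep, , drop = FALSE]
      if (nrow(dup)) { dup$Experiment <- "E2"; maf <- rbind(maf, dup) }
    }
  }
  rownames(maf) <- NULL

  ## ---- clinical --------------------------------------------------------
  rate <- config$survival_rates[match(labels, ets)]
  t_event <- stats::rexp(nT, rate = pmax(rate, 1e-8))
  t_censor <- stats::runif(nT, 0, config$censor_max_years)
  clinical <- data.frame(
    sample_id = tumor_ids,
    patient_id = sprintf("P%04d", seq_len(nT)),
    time_years = pmin(t_event, t_censor),
    event = as.integer(t_event <= t_censor),
    age = round(stats::rnorm(nT, 55, 10)),
    er_status = ifelse(match(labels, ets) %in% setdiff(2:max(2, k - 2), NA),
                       ifelse(stats::runif(nT) < 0.9, "positive", "negative"),
                       ifelse(stats::runif(nT) < 0.3, "positive", "negative")),
    stringsAsFactors = FALSE)

  sample_info <- data.frame(
    sample_id = c(tumor_ids, normal_ids),
    cohort = c(rep("tumor", nT), rep("normal", nN)),
    epitype = c(unname(labels), rep(NA_character_, nN)),
    stringsAsFactors = FALSE)

  ## ---- planted truth ---------------------------------------------------
  meth_universe_classes <- c("cancer_meth", "basal_meth", "luminal_meth",
                             paste0("marker_ET", roles$marker))
  unmeth_universe_classes <- c("cancer_unmeth", "global_hypo", "luminal_hypo",
                               "basal_hypo", "prm2_informative")
  pick <- function(cls) probe_ids[site_class %in% cls]
  truth <- list(
    epitype_labels = labels,
    site_class = site_class,
    class_means = gradient,
    planted_sets = list(
      cancer_methylated = pick(meth_universe_classes),
      cancer_unmethylated = if (nT > 0) pick(unmeth_universe_classes) else character(0),
      et_basal_methylated = pick("basal_meth"),
      et_luminal_methylated = pick("luminal_meth"),
      et_global_hypo_specific = pick("global_hypo"),
      et_luminal_hypo = pick("luminal_hypo"),
      et_basal_hypo_specific = if (nT > 0) pick(c("basal_hypo", "prm2_informative"))
                               else character(0)),
    switch_sets = switch_sets,
    expr_truth = stats::setNames(config$expr_coupling[site_class[ic]], gene[ic]),
    promoter = list(
      PRM1L = list(informative = probe_ids[i1], silenced = prm1_silenced),
      PRM2L = list(informative = probe_ids[i2], unmethylated = prm2_unmeth)),
    amplified = amp_truth,
    roles = roles)
  if (nT == 0)
    truth$planted_sets$cancer_methylated <- character(0)

  structure(list(signals = signals,
                 beta = beta_matrix(beta, assay, normalized = FALSE),
                 annotation = annotation, expression = expression,
                 transcripts = transcripts, copynumber = copynumber,
                 mutations = maf, clinical = clinical,
                 sample_info = sample_info, chrom_lengths = chrom_lengths,
                 truth = truth, config = config),
            class = "methylation_cohort")
}

#' @export
print.methylation_cohort <- function(x, ...) {
  cat(sprintf("methylation_cohort: %d probes, %d tumors, %d normals, %d epitypes\n",
              x$config$n_probes, x$config$n_tumors, x$config$n_normals,
              x$config$n_epitypes))
  invisible(x)
}
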