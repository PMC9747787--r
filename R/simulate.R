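#' Configuration for a synthetic quantitative-metabarcoding experiment
#'
#' Defaults emulate the study design the pipeline targets: ~20 stream sites
#' sampled once (1 L water), one cooler blank per river/sampling day, two
#' PCR negatives, three internal standards at 5/25/50 copies per reaction,
#' and sample-specific read-per-copy slopes of order 10^2-10^3 (lognormal
#' with central 95% mass ~ 120-950, truncated to \[100, 1000\]). True copy
#' concentrations couple to latent fish abundance as
#' copies/L = a * N^gamma * eps with lognormal noise eps; the capture
#' survey binomially thins N with taxon-specific efficiency.
#'
#' @param n_sites Number of field sites (one field sample each).
#' @param n_taxa Number of biological taxa.
#' @param standards Standard specification data.frame (id, copies/reaction).
#' @param slope_meanlog,slope_sdlog,slope_range Lognormal slope
#'   distribution (reads per copy), truncated to `slope_range`.
#' @param copies_per_individual Coupling scale `a` (copies/L per
#'   individual at gamma = 1).
#' @param shedding_sdlog Lognormal sd of per-taxon variation around
#'   `copies_per_individual` (taxa shed eDNA at different rates); 0 makes
#'   all taxa shed equally. Ignored in null scenarios.
#' @param gamma Coupling exponent; `NA` for a null scenario in which copies
#'   are independent of abundance.
#' @param sigma_e Lognormal sd of the copy-abundance coupling noise.
#' @param n_habitats Number of latent habitat groups; sites belong to one
#'   habitat and each taxon prefers one, giving the spatially structured
#'   communities (e.g. upstream vs downstream assemblages) that the
#'   clustering stage is meant to find.
#' @param occupancy_prob Probability a taxon occurs at a site in its
#'   preferred habitat (the zero-inflation complement of the abundance
#'   model).
#' @param occupancy_prob_away Occupancy probability outside the preferred
#'   habitat.
#' @param abundance_mu,abundance_size Negative-binomial mean and size of
#'   latent abundance where the taxon occurs.
#' @param capture_efficiency Per-taxon capture probability in (0, 1];
#'   scalar, vector of length `n_taxa`, or `NULL` to draw Uniform(0.2, 1)
#'   per taxon (heterogeneous gear efficiency).
#' @param mean_mass_g Per-taxon mean individual mass (g); `NULL` draws
#'   lognormal(log 10, 0.5) per taxon.
#' @param biomass_noise_sd Lognormal sd on biomass.
#' @param blank_contamination_rate Mean contaminating copies/L leaking into
#'   a cooler blank (exponential); 0 disables contamination.
#' @param blank_contamination_prob Probability each taxon leaks into a
#'   given blank.
#' @param negative_lambda Poisson mean of stray reads per taxon in PCR
#'   negatives (<= 1 for realistic negligible contamination).
#' @param qpcr_noise_sd Lognormal sd of qPCR measurement noise.
#' @param qpcr_taxa Number of taxa with a simulated qPCR assay.
#' @param depth_multiplier Multiplies every Poisson read mean (sequencing
#'   depth); the per-sample slope absorbs it, so copy estimates are
#'   invariant to it.
#' @param n_blanks Number of cooler blanks (rivers/sampling days).
#' @param seed Integer seed (mandatory; no global random state is reused).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 20, n_taxa = 15,
                       standards = .default_standards(),
                       slope_meanlog = 5.82, slope_sdlog = 0.53,
                       slope_range = c(100, 1000),
                       copies_per_individual = 50, shedding_sdlog = 0.5,
                       gamma = 1, sigma_e = 0.5,
                       n_habitats = 4, occupancy_prob = 0.8,
                       occupancy_prob_away = 0.15, abundance_mu = 20,
                       abundance_size = 1,
                       capture_efficiency = NULL, mean_mass_g = NULL,
                       biomass_noise_sd = 0.2,
                       blank_contamination_rate = 2,
                       blank_contamination_prob = 0.1,
                       negative_lambda = 0.2,
                       qpcr_noise_sd = 0.3, qpcr_taxa = 2,
                       depth_multiplier = 1, n_blanks = 4, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  if (n_taxa < 1 || n_sites < 2) stop("need >= 1 taxon and >= 2 sites", call. = FALSE)
  if (depth_multiplier <= 0) stop("depth_multiplier must be > 0", call. = FALSE)
  if (blank_contamination_rate < 0) stop("blank_contamination_rate must be >= 0", call. = FALSE)
  if (!is.null(capture_efficiency)) {
    if (any(capture_efficiency <= 0 | capture_efficiency > 1)) {
      stop("capture_efficiency must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "sim_config")
}

.truncated_lognorm <- function(n, meanlog, sdlog, range) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- stats::rlnorm(length(need), meanlog, sdlog)
    ok <- draw >= range[1] & draw <= range[2]
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate read counts for one sample
#'
#' Embodies the linearity assumption of quantitative metabarcoding: reads
#' are independent Poisson draws with mean slope x copies, for biological
#' taxa and internal standards alike.
#'
#' @param true_copies_per_reaction Named vector of taxon copies/reaction.
#' @param slope Reads per copy for this sample (> 0).
#' @param standards Standard specification data.frame.
#' @param depth_multiplier Depth factor applied to all Poisson means.
#' @param seed Optional seed; if `NULL`, uses the current RNG stream.
#' @return Named integer vector of reads (taxa then standards).
#' @export
simulate_sample_reads <- function(true_copies_per_reaction, slope, standards,
                                  depth_multiplier = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (any(true_copies_per_reaction < 0)) {
    stop("copies must be non-negative", call. = FALSE)
  }
  mu <- slope * depth_multiplier *
    c(true_copies_per_reaction, stats::setNames(standards$copies_per_reaction,
                                                standards$standard_id))
  stats::setNames(stats::rpois(length(mu), mu), names(mu))
}

#' Simulate a capture survey from true copy concentrations
#'
#' Inverts the coupling model to the latent abundance
#' N = round((copies / a)^(1/gamma)) and binomially thins it with the
#' taxon's capture efficiency; biomass is abundance x mean mass x lognormal
#' noise.
#'
#' @param true_copies Named vector of true copies/L.
#' @param efficiency Capture efficiency per taxon in (0, 1] (recycled).
#' @param copies_per_individual,gamma Coupling parameters.
#' @param mean_mass_g Mean individual mass per taxon (recycled).
#' @param biomass_noise_sd Lognormal sd on biomass (0 = noiseless).
#' @param seed Optional seed.
#' @return List with `abundance` and `biomass_g`, named as `true_copies`.
#' @export
simulate_capture <- function(true_copies, efficiency,
                             copies_per_individual = 50, gamma = 1,
                             mean_mass_g = 10, biomass_noise_sd = 0,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(efficiency <= 0 | efficiency > 1)) {
    stop("efficiency must lie in (0, 1]", call. = FALSE)
  }
  k <- length(true_copies)
  efficiency <- rep_len(efficiency, k)
  mean_mass_g <- rep_len(mean_mass_g, k)
  latent_n <- as.integer(round((true_copies / copies_per_individual)^(1 / gamma)))
  abundance <- stats::rbinom(k, latent_n, efficiency)
  noise <- if (biomass_noise_sd > 0) {
    stats::rlnorm(k, 0, biomass_noise_sd)
  } else rep(1, k)
  biomass <- abundance * mean_mass_g * noise
  list(abundance = stats::setNames(abundance, names(true_copies)),
       biomass_g = stats::setNames(biomass, names(true_copies)),
       latent_n = stats::setNames(latent_n, names(true_copies)))
}

#' Simulate a complete quantitative-metabarcoding experiment
#'
#' Generates everything the pipeline consumes, with known ground truth:
#' a taxon x sample read-count table including internal-standard rows,
#' cooler blanks (standards plus rare exponential contamination leaks) and
#' PCR negatives (stray reads only, no standards); a run manifest; a
#' capture table; a qPCR table for a subset of taxa; and the `SimTruth`
#' ledger of true copies, slopes and coupling parameters.
#'
#' @param config A [sim_config()].
#' @return Object of class `edna_simulation` with elements `counts`,
#'   `manifest`, `capture`, `qpcr`, `truth`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- config$n_taxa; ns <- config$n_sites
  taxa <- sprintf("taxon%02d", seq_len(nt))
  sites <- sprintf("st%02d", seq_len(ns))
  rivers <- sprintf("river%d", rep_len(seq_len(config$n_blanks), ns))
  field_ids <- paste0("smp_", sites)
  blank_ids <- paste0("blank_river", seq_len(config$n_blanks))
  neg_ids <- c("pcr_neg1", "pcr_neg2")

  # latent abundance: zero-inflated negative binomial per site x taxon,
  # with habitat-structured occupancy (sites and taxa belong to habitats)
  site_habitat <- rep_len(seq_len(config$n_habitats), ns)
  taxon_habitat <- sample(seq_len(config$n_habitats), nt, replace = TRUE)
  p_occ <- matrix(config$occupancy_prob_away, nt, ns)
  p_occ[outer(taxon_habitat, site_habitat, "==")] <- config$occupancy_prob
  occ <- matrix(stats::rbinom(nt * ns, 1, p_occ), nt, ns)
  latent_n <- occ * matrix(stats::rnbinom(nt * ns, mu = config$abundance_mu,
                                          size = config$abundance_size), nt, ns)
  dimnames(latent_n) <- list(taxa, sites)

  # true copies/L: coupled (copies = a_t * N^gamma * eps) or null (independent)
  eps <- matrix(stats::rlnorm(nt * ns, 0, config$sigma_e), nt, ns)
  if (is.na(config$gamma)) {
    # null scenario: copy concentrations iid across cells, independent of
    # abundance and free of the habitat/taxon structure that abundance
    # carries, so pooled copies-vs-capture tests see true independence
    shedding <- rep(config$copies_per_individual, nt)
    indep_occ <- matrix(stats::rbinom(nt * ns, 1, mean(p_occ)), nt, ns)
    indep_n <- matrix(stats::rnbinom(nt * ns, mu = config$abundance_mu,
                                     size = config$abundance_size), nt, ns)
    copies_L <- config$copies_per_individual * indep_occ * indep_n * eps
  } else {
    shedding <- config$copies_per_individual *
      stats::rlnorm(nt, 0, config$shedding_sdlog)
    copies_L <- shedding * latent_n^config$gamma * eps
    copies_L[latent_n == 0] <- 0
  }
  dimnames(copies_L) <- list(taxa, sites)

  # manifest
  samples <- rbind(
    data.frame(sample_id = field_ids, site_id = sites, river_id = rivers,
               role = "field", stringsAsFactors = FALSE),
    data.frame(sample_id = blank_ids,
               site_id = paste0("blank_site", seq_len(config$n_blanks)),
               river_id = sprintf("river%d", seq_len(config$n_blanks)),
               role = "cooler_blank", stringsAsFactors = FALSE),
    data.frame(sample_id = neg_ids, site_id = c("none", "none"),
               river_id = c("none", "none"), role = "pcr_negative",
               stringsAsFactors = FALSE)
  )
  blank_map <- stats::setNames(paste0("blank_", rivers), field_ids)
  manifest <- run_manifest(samples, blank_map, standards = config$standards,
                           seed = config$seed)

  meta <- manifest$samples
  vol_factor <- function(sid) {
    m <- meta[meta$sample_id == sid, ]
    m$water_volume_L * m$template_volume_uL / m$elution_volume_uL
  }

  calibrated <- c(field_ids, blank_ids)
  slopes <- stats::setNames(
    .truncated_lognorm(length(calibrated), config$slope_meanlog,
                       config$slope_sdlog, config$slope_range), calibrated)

  counts <- matrix(0L, nt + nrow(config$standards),
                   length(c(calibrated, neg_ids)),
                   dimnames = list(c(taxa, config$standards$standard_id),
                                   c(calibrated, neg_ids)))
  blank_copies_L <- matrix(0, nt, config$n_blanks,
                           dimnames = list(taxa, blank_ids))
  for (sid in field_ids) {
    site <- meta$site_id[meta$sample_id == sid]
    cpr <- copies_L[, site] * vol_factor(sid)
    counts[, sid] <- simulate_sample_reads(stats::setNames(cpr, taxa),
                                           slopes[sid], config$standards,
                                           config$depth_multiplier)
  }
  for (bid in blank_ids) {
    contam <- numeric(nt)
    if (config$blank_contamination_rate > 0) {
      leaks <- stats::rbinom(nt, 1, config$blank_contamination_prob) == 1
      contam[leaks] <- stats::rexp(sum(leaks),
                                   rate = 1 / config$blank_contamination_rate)
    }
    blank_copies_L[, bid] <- contam
    cpr <- contam * vol_factor(bid)
    counts[, bid] <- simulate_sample_reads(stats::setNames(cpr, taxa),
                                           slopes[bid], config$standards,
                                           config$depth_multiplier)
  }
  for (nid in neg_ids) {
    counts[taxa, nid] <- stats::rpois(nt, config$negative_lambda *
                                        config$depth_multiplier)
  }

  # capture survey: binomial thinning of latent abundance
  eff <- if (is.null(config$capture_efficiency)) {
    stats::runif(nt, 0.2, 1)
  } else rep_len(config$capture_efficiency, nt)
  mass <- if (is.null(config$mean_mass_g)) {
    stats::rlnorm(nt, log(10), 0.5)
  } else rep_len(config$mean_mass_g, nt)
  cap_rows <- NULL
  for (s in sites) {
    ab <- stats::rbinom(nt, latent_n[, s], eff)
    noise <- stats::rlnorm(nt, 0, config$biomass_noise_sd)
    bm <- ab * mass * noise
    keep <- ab > 0
    if (any(keep)) {
      cap_rows <- rbind(cap_rows, data.frame(
        site_id = s, taxon = taxa[keep], abundance = ab[keep],
        biomass_g = bm[keep], stringsAsFactors = FALSE))
    }
  }
  capture <- cap_rows %||% data.frame(site_id = character(), taxon = character(),
                                      abundance = integer(), biomass_g = numeric(),
                                      stringsAsFactors = FALSE)

  # qPCR assays for a taxon subset (those with the most detections)
  nq <- min(config$qpcr_taxa, nt)
  q_taxa <- taxa[order(rowSums(copies_L > 0), decreasing = TRUE)][seq_len(nq)]
  qpcr <- do.call(rbind, lapply(q_taxa, function(t) {
    data.frame(taxon = t, site_id = sites,
               qpcr_copies_L = copies_L[t, ] *
                 stats::rlnorm(ns, 0, config$qpcr_noise_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(qpcr) <- NULL

  truth <- list(copies_L = copies_L, blank_copies_L = blank_copies_L,
                slopes = slopes, abundance = latent_n,
                site_habitat = stats::setNames(site_habitat, sites),
                taxon_habitat = stats::setNames(taxon_habitat, taxa),
                capture_efficiency = stats::setNames(eff, taxa),
                mean_mass_g = stats::setNames(mass, taxa),
                coupling = list(a = config$copies_per_individual,
                                shedding = stats::setNames(shedding, taxa),
                                gamma = config$gamma, sigma_e = config$sigma_e))
  structure(list(counts = counts, manifest = manifest, capture = capture,
                 qpcr = qpcr, truth = truth, config = config),
            class = "edna_simulation")
}

#' @export
print.edna_simulation <- function(x, ...) {
  cat(sprintf("synthetic qMiSeq experiment: %d taxa x %d sites, %d cooler blanks, %d PCR negatives\n",
              x$config$n_taxa, x$config$n_sites, x$config$n_blanks, 2L))
  cat(sprintf("true slopes %.0f-%.0f reads/copy; coupling gamma = %s\n",
              min(x$truth$slopes), max(x$truth$slopes),
              format(x$config$gamma)))
  invisible(x)
}

#' Write all artifacts of a simulated experiment to a directory
#'
#' @param sim An `edna_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.yaml"))
  write_capture_table(sim$capture, file.path(dir, "capture.tsv"))
  utils::write.table(sim$qpcr, file.path(dir, "qpcr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$copies_L <- as.data.frame(truth$copies_L)
  truth$blank_copies_L <- as.data.frame(truth$blank_copies_L)
  truth$abundance <- as.data.frame(truth$abundance)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
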