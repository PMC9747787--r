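# All permutations of 1..n as an (n!) x n integer matrix; n <= 8 keeps this
# small enough for exact tests. Cached, since exact tests reuse the matrix.
.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(n) {
  key <- as.character(n)
  cached <- .perm_cache[[key]]
  if (!is.null(cached)) return(cached)
  out <- .permutations_build(n)
  .perm_cache[[key]] <- out
  out
}

.permutations_build <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations_build(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    block <- cbind(rep.int(i, nrow(sub)), sub + (sub >= i))
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Kendall S statistic (concordant minus discordant pairs) for fixed x sign
# matrix against one or many y vectors. sx: upper-triangle sign vector of x.
.kendall_S <- function(sx, y, pairs) {
  sy <- sign(y[pairs[, 1]] - y[pairs[, 2]])
  sum(sx * sy)
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Counts concordant and discordant pairs over all n*(n-1)/2 pairs and
#' normalizes with the tie correction (tau-b). The p-value is exact by full
#' enumeration of permutations of `y` when `n <= exact_n` (default 8), else
#' from the normal approximation with the tie-adjusted variance of S.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact_n Largest n for which the exact permutation p is computed.
#' @return Object of class `tau_result`: `tau_b`, `p_value`, `p_method`
#'   (`"exact"` or `"normal"`), `n_pairs_used`, `concordant`, `discordant`,
#'   `ties_x`, `ties_y`. If either vector is constant, `tau_b` and
#'   `p_value` are `NA` with `reason = "constant_input"`.
#' @export
kendall_tau <- function(x, y, exact_n = 8) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  res <- list(tau_b = NA_real_, p_value = NA_real_, p_method = NA_character_,
              n_pairs_used = n, concordant = NA_integer_,
              discordant = NA_integer_, ties_x = NA_integer_,
              ties_y = NA_integer_, reason = NA_character_)
  class(res) <- "tau_result"
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    res$reason <- "constant_input"
    return(res)
  }
  pairs <- t(utils::combn(n, 2))
  sx <- sign(x[pairs[, 1]] - x[pairs[, 2]])
  sy <- sign(y[pairs[, 1]] - y[pairs[, 2]])
  conc <- sum(sx * sy > 0)
  disc <- sum(sx * sy < 0)
  tx <- sum(sx == 0)
  ty <- sum(sy == 0)
  n0 <- nrow(pairs)
  S <- conc - disc
  tau_b <- S / sqrt((n0 - tx) * (n0 - ty))

  if (n <= exact_n) {
    perms <- .permutations(n)
    # S for every permutation of y against fixed x, vectorized over perms
    Y <- matrix(y[perms], nrow(perms), n)
    Sperm <- numeric(nrow(perms))
    for (p in seq_len(n0)) {
      Sperm <- Sperm + sx[p] * sign(Y[, pairs[p, 1]] - Y[, pairs[p, 2]])
    }
    p_value <- mean(abs(Sperm) >= abs(S) - 1e-9)
    p_method <- "exact"
  } else {
    tie_sizes <- function(v) {
      t <- table(v)
      as.numeric(t[t > 1])
    }
    tt <- tie_sizes(x); uu <- tie_sizes(y)
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tt * (tt - 1) * (2 * tt + 5))
    vu <- sum(uu * (uu - 1) * (2 * uu + 5))
    v1 <- sum(tt * (tt - 1)) * sum(uu * (uu - 1)) / (2 * n * (n - 1))
    v2 <- sum(tt * (tt - 1) * (tt - 2)) * sum(uu * (uu - 1) * (uu - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(varS)
    p_value <- 2 * stats::pnorm(-abs(z))
    p_method <- "normal"
  }
  res$tau_b <- tau_b
  res$p_value <- p_value
  res$p_method <- p_method
  res$concordant <- as.integer(conc)
  res$discordant <- as.integer(disc)
  res$ties_x <- as.integer(tx)
  res$ties_y <- as.integer(ty)
  res
}

#' @export
print.tau_result <- function(x, ...) {
  if (is.na(x$tau_b)) {
    cat("Kendall tau-b: undefined (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("Kendall tau-b = %.4f, p = %.4g (%s), n = %d\n",
                x$tau_b, x$p_value, x$p_method, x$n_pairs_used))
  }
  invisible(x)
}

# Long (site, taxon) pairing of copies with a capture response.
.paired_rows <- function(copies, capture, response,
                         drop_double_zero = TRUE) {
  # capture tables list positive catches only: a site absent from the table
  # was surveyed with zero catch, so the pair universe is the copy table's
  sites <- colnames(copies)
  taxa <- intersect(rownames(copies), unique(capture$taxon))
  cap <- capture[capture$site_id %in% sites & capture$taxon %in% taxa, ]
  key <- paste(cap$site_id, cap$taxon, sep = "\r")
  grid <- expand.grid(site_id = sites, taxon = taxa, stringsAsFactors = FALSE)
  idx <- match(paste(grid$site_id, grid$taxon, sep = "\r"), key)
  resp <- ifelse(is.na(idx), 0, cap[[response]][idx])
  cop <- copies[cbind(grid$taxon, grid$site_id)]
  keep <- !is.na(cop)
  if (drop_double_zero) keep <- keep & !(cop == 0 & resp == 0)
  data.frame(site_id = grid$site_id[keep], taxon = grid$taxon[keep],
             copies = cop[keep], response = resp[keep],
             stringsAsFactors = FALSE)
}

#' Kendall correlation of copy concentrations against capture data
#'
#' Pools (site, taxon) rows of copies/L against capture abundance or
#' biomass and computes Kendall tau-b; with a site clustering, also one tau
#' per cluster. Double-zero pairs (taxon absent in both methods) are
#' excluded by default since they would manufacture concordance.
#'
#' @param copies Taxa x site matrix of copies/L.
#' @param capture Capture data.frame ([read_capture_table()]).
#' @param clusters Optional `edna_clustering` (or named integer vector of
#'   site labels).
#' @param response `"abundance"` or `"biomass"`.
#' @param drop_double_zero Exclude pairs that are zero in both methods.
#' @return data.frame with one row for the pooled test and one per cluster:
#'   `scope`, `tau_b`, `p_value`, `n_pairs`.
#' @export
correlate_copies_vs_capture <- function(copies, capture, clusters = NULL,
                                        response = c("abundance", "biomass"),
                                        drop_double_zero = TRUE) {
  response <- match.arg(response)
  rows <- .paired_rows(copies, capture,
                       if (response == "biomass") "biomass_g" else "abundance",
                       drop_double_zero)
  run_tau <- function(df, scope) {
    if (nrow(df) < 3) {
      warning(sprintf("scope %s has < 3 usable pairs; tau undefined", scope))
      return(data.frame(scope = scope, tau_b = NA_real_, p_value = NA_real_,
                        n_pairs = nrow(df), stringsAsFactors = FALSE))
    }
    tr <- kendall_tau(df$copies, df$response)
    data.frame(scope = scope, tau_b = tr$tau_b, p_value = tr$p_value,
               n_pairs = nrow(df), stringsAsFactors = FALSE)
  }
  out <- run_tau(rows, "all_sites")
  if (!is.null(clusters)) {
    labels <- if (inherits(clusters, "edna_clustering")) clusters$labels else clusters
    for (g in sort(unique(labels))) {
      in_cluster <- names(labels)[labels == g]
      out <- rbind(out, run_tau(rows[rows$site_id %in% in_cluster, ],
                                paste0("cluster_", g)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Select taxa detected at enough sites by both methods
#'
#' A taxon enters the per-taxon models only if it was detected (value > 0)
#' at `min_sites` or more sites by the metabarcoding approach AND by the
#' capture survey.
#'
#' @param copies Taxa x site matrix of copies/L.
#' @param capture Capture data.frame.
#' @param min_sites Minimum detection sites per method, default 3.
#' @return Character vector of taxon ids.
#' @export
select_taxa_for_models <- function(copies, capture, min_sites = 3) {
  taxa <- intersect(rownames(copies), unique(capture$taxon))
  keep <- vapply(taxa, function(t) {
    edna_sites <- sum(copies[t, ] > 0, na.rm = TRUE)
    cap <- capture[capture$taxon == t & capture$abundance > 0, ]
    edna_sites >= min_sites && length(unique(cap$site_id)) >= min_sites
  }, logical(1))
  taxa[keep]
}

#' Negative-binomial GLM of copy number on a capture predictor
#'
#' Fits copies ~ predictor with a log link and negative-binomial response
#' (maximum likelihood, including the dispersion theta). Copy
#' concentrations are rounded to the nearest integer to form the count
#' response; a warning is raised if rounding moves values by more than 1%
#' on average.
#'
#' @param copies Copies/L per observation (response).
#' @param predictor Capture abundance or biomass per observation.
#' @param id Optional taxon or group label carried into the result.
#' @param predictor_name Label (`"abundance"` or `"biomass"`).
#' @return Object of class `glm_nb_result`: `id`, `predictor`, `estimate`,
#'   `se`, `z`, `p`, `theta`, `n_obs`, `converged`, `reason`.
#' @export
fit_glm_nb <- function(copies, predictor, id = "", predictor_name = "abundance") {
  if (length(copies) != length(predictor)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(copies) & !is.na(predictor)
  copies <- copies[ok]; predictor <- predictor[ok]
  if (length(copies) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(predictor)) == 1) stop("predictor is constant", call. = FALSE)
  y <- round(copies)
  nz <- copies != 0
  if (any(nz) && mean(abs(y[nz] - copies[nz]) / copies[nz]) > 0.01) {
    warning("rounding copies to integers changed values by > 1% on average")
  }
  out <- list(id = id, predictor = predictor_name, estimate = NA_real_,
              se = NA_real_, z = NA_real_, p = NA_real_, theta = NA_real_,
              n_obs = length(y), converged = FALSE, reason = NA_character_)
  class(out) <- "glm_nb_result"
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(y ~ predictor)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out$reason <- conditionMessage(fit)
    return(out)
  }
  cf <- summary(fit)$coefficients
  out$estimate <- cf["predictor", "Estimate"]
  out$se <- cf["predictor", "Std. Error"]
  out$z <- cf["predictor", "z value"]
  out$p <- cf["predictor", "Pr(>|z|)"]
  out$theta <- fit$theta
  out$converged <- isTRUE(fit$converged) && is.finite(out$se)
  if (!out$converged) out$reason <- "nonconvergence"
  out
}

#' @export
print.glm_nb_result <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("GLM-nb [%s ~ %s]: did not converge (%s)\n",
                x$id, x$predictor, x$reason))
  } else {
    cat(sprintf("GLM-nb [%s ~ %s]: estimate %.4g (SE %.3g, z %.2f, p %.3g), theta %.3g, n %d\n",
                x$id, x$predictor, x$estimate, x$se, x$z, x$p, x$theta, x$n_obs))
  }
  invisible(x)
}

#' Per-taxon negative-binomial GLMs of copies on capture data
#'
#' For each selected taxon, fits [fit_glm_nb()] of site-level copies on the
#' chosen capture predictor.
#'
#' @param copies Taxa x site matrix of copies/L.
#' @param capture Capture data.frame.
#' @param taxa Taxon ids to model (e.g. from [select_taxa_for_models()]).
#' @param response `"abundance"` or `"biomass"`.
#' @return data.frame with one row per taxon.
#' @export
fit_taxon_glms <- function(copies, capture, taxa,
                           response = c("abundance", "biomass")) {
  response <- match.arg(response)
  col <- if (response == "biomass") "biomass_g" else "abundance"
  do.call(rbind, lapply(taxa, function(t) {
    rows <- .paired_rows(copies[t, , drop = FALSE], capture, col,
                         drop_double_zero = FALSE)
    r <- tryCatch(fit_glm_nb(rows$copies, rows$response, id = t,
                             predictor_name = response),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    as.data.frame(unclass(r), stringsAsFactors = FALSE)
  }))
}

#' Per-guild pooled negative-binomial GLMs
#'
#' Pools the (site, taxon) rows of every member taxon of each group (e.g.
#' benthic vs non-benthic fishes) and fits one GLM-nb per group and
#' predictor.
#'
#' @param copies Taxa x site matrix of copies/L.
#' @param capture Capture data.frame.
#' @param groups Named list mapping group id to member taxon ids.
#' @param response `"abundance"` or `"biomass"`.
#' @return data.frame with one row per group (groups with < 3 usable rows
#'   are skipped with a warning).
#' @export
fit_group_glms <- function(copies, capture, groups,
                           response = c("abundance", "biomass")) {
  response <- match.arg(response)
  col <- if (response == "biomass") "biomass_g" else "abundance"
  out <- NULL
  for (g in names(groups)) {
    members <- intersect(groups[[g]], rownames(copies))
    rows <- .paired_rows(copies[members, , drop = FALSE], capture, col,
                         drop_double_zero = FALSE)
    if (nrow(rows) < 3) {
      warning(sprintf("group %s has < 3 rows; skipped", g))
      next
    }
    r <- fit_glm_nb(rows$copies, rows$response, id = g,
                    predictor_name = response)
    out <- rbind(out, as.data.frame(unclass(r), stringsAsFactors = FALSE))
  }
  out
}

#' Cross-validate metabarcoding copies against species-specific qPCR
#'
#' Ordinary least-squares regression (with intercept) of metabarcoding
#' concentrations on qPCR concentrations of the same samples; a slope below
#' one indicates the metabarcoding estimates run lower than qPCR. On the
#' log10 scale, pairs containing any zero are dropped with a warning.
#'
#' @param qmiseq Metabarcoding copy concentrations.
#' @param qpcr qPCR copy concentrations (paired).
#' @param scale `"raw"` or `"log10"`.
#' @return Object of class `qpcr_regression`: `slope`, `intercept`, `r2`,
#'   `p_value`, `n`, `scale`.
#' @export
compare_with_qpcr <- function(qmiseq, qpcr, scale = c("raw", "log10")) {
  scale <- match.arg(scale)
  if (length(qmiseq) != length(qpcr)) stop("length mismatch", call. = FALSE)
  ok <- !is.na(qmiseq) & !is.na(qpcr)
  x <- qpcr[ok]; y <- qmiseq[ok]
  if (scale == "log10") {
    nz <- x > 0 & y > 0
    if (any(!nz)) warning(sprintf("%d pairs with zeros dropped on log10 scale", sum(!nz)))
    x <- log10(x[nz]); y <- log10(y[nz])
  }
  if (length(x) < 3) stop("need at least 3 usable pairs", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x), scale = scale),
            class = "qpcr_regression")
}

#' @export
print.qpcr_regression <- function(x, ...) {
  cat(sprintf("qPCR cross-validation (%s scale): slope %.3f, intercept %.3g, R2 %.3f, p %.3g, n %d\n",
              x$scale, x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}
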