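#' Holm (or Benjamini-Hochberg) p-value adjustment
#'
#' Step-down Holm adjustment with enforced monotonicity, capped at 1;
#' Benjamini-Hochberg is available as the alternative multiplicity
#' method.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"holm"` (family-wise) or `"bh"` (false discovery
#'   rate).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("holm", "bh")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("adjust_pvalues: p-values must lie in [0, 1] and be non-missing")
  p.adjust(p, method = if (method == "holm") "holm" else "BH")
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(a) - mean(b)) / s_pooled`, with
#' the pooled SD weighted by `n - 1` in each sample. The magnitude is
#' returned by default (the usual reporting convention for screening);
#' set `signed = TRUE` for the signed value.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param signed Return the signed d instead of its magnitude.
#' @return Scalar effect size.
#' @export
cohens_d <- function(a, b, signed = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("cohens_d: both samples need at least two observations")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0)
    stop("cohens_d: pooled standard deviation is zero")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  if (signed) d else abs(d)
}

#' Paired Wilcoxon signed-rank test (normal approximation)
#'
#' Signed-rank test on paired differences with zero differences
#' dropped, average ranks for ties, tie-corrected variance and no
#' continuity correction; returns a signed Z (negative when `x` tends
#' below `y`) and the two-sided normal-approximation p-value.
#'
#' @param x,y Paired numeric vectors of equal length >= 5.
#' @return List with `Z`, `p`, `n_used` (nonzero differences) and
#'   `degenerate` (TRUE when every difference is zero).
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y))
    stop("paired_wilcoxon: x and y must have equal length")
  if (length(x) < 5L)
    stop("paired_wilcoxon: need at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("paired_wilcoxon: all paired differences are zero; ",
            "degenerate result")
    return(list(Z = NA_real_, p = NA_real_, n_used = 0L, degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_pos - mu) / sqrt(sigma2)
  list(Z = z, p = 2 * pnorm(-abs(z)), n_used = n, degenerate = FALSE)
}

# Aggregate a long count table to one (count, area) pair per
# subject-region, keeping group and litter metadata.
aggregate_subject_region <- function(records) {
  key <- paste(records$subject_id, records$region, sep = "\r")
  cnt <- tapply(records$count, key, sum)
  ar <- tapply(records$area_mm2, key, sum)
  meta <- unique(records[, c("subject_id", "group", "litter_id")])
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  out <- data.frame(
    subject_id = vapply(parts, `[`, "", 1L),
    region = vapply(parts, `[`, "", 2L),
    count = as.integer(unname(cnt)),
    area = as.numeric(unname(ar)),
    stringsAsFactors = FALSE
  )
  out <- merge(out, meta, by = "subject_id", sort = FALSE)
  out$group <- factor(out$group)
  out$litter_id <- factor(out$litter_id)
  out
}

nb_mixed_lrt <- function(dat, with_region, with_subject, label) {
  rhs_full <- "group + (1 | litter_id) + offset(log(area))"
  rhs_null <- "1 + (1 | litter_id) + offset(log(area))"
  if (with_region) {
    rhs_full <- paste("region +", rhs_full)
    rhs_null <- paste("region +", rhs_null)
  }
  if (with_subject) {
    rhs_full <- paste(rhs_full, "+ (1 | subject_id)")
    rhs_null <- paste(rhs_null, "+ (1 | subject_id)")
  }
  fit_one <- function(rhs) {
    f <- suppressWarnings(glmmTMB::glmmTMB(
      stats::as.formula(paste("count ~", rhs)),
      family = glmmTMB::nbinom2, data = dat,
      control = glmmTMB::glmmTMBControl(
        optCtrl = list(iter.max = 500, eval.max = 500))
    ))
    conv_ok <- isTRUE(f$fit$convergence == 0)
    pd <- f$sdr$pdHess
    if (!conv_ok || !isTRUE(pd))
      stop("negative-binomial mixed model did not converge for ", label)
    f
  }
  full <- fit_one(rhs_full)
  null <- fit_one(rhs_null)
  chi2 <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  beta <- glmmTMB::fixef(full)$cond
  est <- unname(beta[grep("^group", names(beta))][1])
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       estimate = est, n_obs = nrow(dat))
}

#' Fit the per-region activation model
#'
#' Negative-binomial (variance mu + mu^2/theta) regression of
#' subject-level total counts on treatment group, with a litter random
#' intercept and log total ROI area as offset, so the treatment effect
#' acts multiplicatively on density. The treatment term is tested by a
#' likelihood-ratio chi-square with 1 df against the model without it.
#' With one aggregated observation per subject, the individual-level
#' random effect is absorbed by the NB dispersion.
#'
#' @param records Count table restricted to (or filtered by `region`
#'   to) a single region.
#' @param region Optional region label to filter on.
#' @param alpha Significance level used to call the direction of the
#'   effect.
#' @return Object of class `region_stat`: region, chi2, df, p,
#'   treatment log-fold-change estimate, direction
#'   (`"<group>_higher"` or `"none"`), n_obs, degenerate flag.
#' @export
fit_region_model <- function(records, region = NULL, alpha = 0.05) {
  if (!is.null(region)) records <- records[records$region == region, ]
  regs <- unique(records$region)
  if (length(regs) != 1L)
    stop("fit_region_model: records must cover exactly one region ",
         "(got ", length(regs), "); use fit_network_model for pooled fits")
  dat <- aggregate_subject_region(records)
  groups <- levels(dat$group)
  if (length(groups) != 2L)
    stop("fit_region_model [", regs, "]: exactly two groups required")
  n_by_group <- table(dat$group)
  if (any(n_by_group < 2L))
    stop("fit_region_model [", regs, "]: need >= 2 subjects per group")
  if (nlevels(dat$litter_id) < 2L)
    stop("fit_region_model [", regs, "]: need >= 2 litters")
  zero_group <- vapply(groups, function(g) all(dat$count[dat$group == g] == 0),
                       TRUE)
  if (any(zero_group)) {
    warning("fit_region_model [", regs, "]: all-zero counts in group ",
            paste(groups[zero_group], collapse = ", "), "; degenerate fit")
    return(structure(list(region = regs, chi2 = NA_real_, df = 1L,
                          p = NA_real_, estimate = NA_real_,
                          direction = "none", n_obs = nrow(dat),
                          degenerate = TRUE), class = "region_stat"))
  }
  res <- nb_mixed_lrt(dat, with_region = FALSE, with_subject = FALSE,
                      label = paste0("region ", regs))
  direction <- if (!is.na(res$p) && res$p < alpha) {
    if (res$estimate > 0) paste0(groups[2], "_higher")
    else paste0(groups[1], "_higher")
  } else "none"
  structure(c(list(region = regs), res,
              list(direction = direction, degenerate = FALSE)),
            class = "region_stat")
}

#' @export
print.region_stat <- function(x, ...) {
  cat(sprintf("<region_stat> %s: chi2(%d) = %.3f, p = %.4g, lfc = %.3f [%s]\n",
              x$region, x$df, x$chi2, x$p, x$estimate, x$direction))
  invisible(x)
}

#' Fit a pooled network-level activation model
#'
#' One negative-binomial mixed model over all subject-by-region
#' observations of a named region set: treatment fixed effect, region
#' fixed covariate (when more than one region), litter and subject
#' random intercepts (the subject intercept is included only when
#' subjects contribute more than one observation), and log-area offset.
#' The treatment term is tested by a 1-df likelihood-ratio chi-square.
#'
#' @param records Count table.
#' @param regions Regions making up the network; default all in
#'   `records`.
#' @param label Network name for reporting.
#' @return Object of class `network_stat`: label, chi2, df, p,
#'   estimate, n_obs, n_regions.
#' @export
fit_network_model <- function(records, regions = NULL, label = "network") {
  if (!is.null(regions)) {
    missing_regions <- setdiff(regions, unique(records$region))
    if (length(missing_regions))
      stop("fit_network_model [", label, "]: regions absent from data: ",
           paste(missing_regions, collapse = ", "))
    records <- records[records$region %in% regions, ]
  }
  dat <- aggregate_subject_region(records)
  dat$region <- factor(dat$region)
  n_regions <- nlevels(dat$region)
  with_subject <- any(table(dat$subject_id) > 1L)
  res <- nb_mixed_lrt(dat, with_region = n_regions > 1L,
                      with_subject = with_subject,
                      label = paste0("network ", label))
  structure(c(list(label = label, n_regions = n_regions), res),
            class = "network_stat")
}

#' @export
print.network_stat <- function(x, ...) {
  cat(sprintf("<network_stat> %s (%d regions): chi2(%d, %d) = %.3f, p = %.4g\n",
              x$label, x$n_regions, x$df, x$n_obs, x$chi2, x$p))
  invisible(x)
}

#' Region-by-region activation scan
#'
#' Fits [fit_region_model()] for every region, applies the multiplicity
#' adjustment across the whole family of analyzed regions, and computes
#' Cohen's d on subject densities for regions in the screening band
#' `0.05 < p < 0.1` (the near-significance band screened for large
#' effects).
#'
#' @param records Full count table.
#' @param adjust Multiplicity method passed to [adjust_pvalues()].
#' @param screen_lo,screen_hi Raw-p screening band for Cohen's d.
#' @return Data frame: region, chi2, df, p, p_adjusted, cohens_d,
#'   direction, lfc, degenerate.
#' @export
region_scan <- function(records, adjust = "holm",
                        screen_lo = 0.05, screen_hi = 0.1) {
  regions <- unique(records$region)
  dens <- compute_density(records)
  groups <- unique(records$group)
  fits <- lapply(regions, function(rg) fit_region_model(records, region = rg))
  p_raw <- vapply(fits, function(f) f$p, 0)
  ok <- !is.na(p_raw)
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[ok] <- adjust_pvalues(p_raw[ok], method = adjust)
  d_vals <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) {
    if (ok[i] && p_raw[i] > screen_lo && p_raw[i] < screen_hi) {
      x <- density_matrix(dens, group = groups[1])[, regions[i]]
      y <- density_matrix(dens, group = groups[2])[, regions[i]]
      d_vals[i] <- tryCatch(cohens_d(x, y), error = function(e) NA_real_)
    }
  }
  data.frame(
    region = regions,
    chi2 = vapply(fits, function(f) f$chi2, 0),
    df = vapply(fits, function(f) f$df, 0L),
    p = p_raw,
    p_adjusted = p_adj,
    cohens_d = d_vals,
    direction = vapply(fits, function(f) f$direction, ""),
    lfc = vapply(fits, function(f) f$estimate, 0),
    degenerate = vapply(fits, function(f) isTRUE(f$degenerate), TRUE),
    stringsAsFactors = FALSE
  )
}
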