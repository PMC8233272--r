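# Per-region count statistics: negative-binomial GLM per region, Dunnett
# many-to-one contrasts against the control group, FDR across regions,
# and model diagnostics (deviance residuals, Cook's distance, low-count
# screen).

#' Fit per-region negative-binomial GLMs
#'
#' For every region, fits a negative-binomial regression with log link on
#' the group indicators (`count ~ group`), dispersion theta estimated by
#' maximum likelihood. The control group is the reference level, so the
#' coefficients are log fold changes of each treatment versus control.
#' Regions whose counts are all zero, or where the fit does not converge,
#' are flagged and excluded from inference (never silently dropped).
#'
#' @param counts count data.frame (`animal_id, group, region_id, count`),
#'   one row per animal x region.
#' @param control name of the control group.
#' @return An object of class `fos_region_fit` with per-region fits and
#'   flags; see [coef.fos_region_fit()], [summary.fos_region_fit()].
#' @export
fit_region_nbglm <- function(counts, control) {
  groups <- unique(counts$group)
  if (!(control %in% groups)) stop("control group not present: ", control)
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(table(counts$group[!duplicated(counts$animal_id)]) < 2))
    stop("need >= 2 animals per group")
  counts$group <- stats::relevel(factor(counts$group), ref = control)
  regions <- sort(unique(counts$region_id))
  fits <- setNames(vector("list", length(regions)), as.character(regions))
  status <- setNames(rep("ok", length(regions)), as.character(regions))
  for (r in as.character(regions)) {
    sub <- counts[counts$region_id == as.integer(r), ]
    if (all(sub$count == 0)) { status[r] <- "all_zero"; next }
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(count ~ group, data = sub,
                                    control = stats::glm.control(maxit = 50))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { status[r] <- "not_converged"; next }
    fits[[r]] <- fit
  }
  structure(list(fits = fits, status = status, control = control,
                 groups = levels(counts$group), counts = counts),
            class = "fos_region_fit")
}

#' @export
print.fos_region_fit <- function(x, ...) {
  cat(sprintf("<fos_region_fit> %d regions (%d fitted), control '%s', groups: %s\n",
              length(x$fits), sum(x$status == "ok"), x$control,
              paste(x$groups, collapse = ", ")))
  invisible(x)
}

#' @export
coef.fos_region_fit <- function(object, ...) {
  trt <- setdiff(object$groups, object$control)
  out <- matrix(NA_real_, length(object$fits), length(trt),
                dimnames = list(names(object$fits), trt))
  for (r in names(object$fits)) {
    f <- object$fits[[r]]
    if (is.null(f)) next
    cf <- coef(f)
    out[r, ] <- cf[paste0("group", trt)] / log(2)  # log2 fold change
  }
  out
}

#' @export
summary.fos_region_fit <- function(object, ...) {
  l2fc <- coef(object)
  theta <- vapply(object$fits, function(f)
    if (is.null(f)) NA_real_ else f$theta, 0)
  data.frame(region_id = as.integer(names(object$fits)),
             status = unname(object$status), dispersion = unname(theta),
             l2fc, check.names = FALSE, row.names = NULL)
}

#' Dunnett many-to-one adjustment within each region model
#'
#' For every fitted region model, compares each treatment group against
#' the control using the joint distribution of the Wald contrast
#' statistics (Wald covariance inflated by the fit's Pearson dispersion,
#' floored at 1 — a quasi-likelihood correction that keeps the test
#' calibrated at few animals per group): a multivariate t with the
#' model's estimated contrast
#' correlation and the residual degrees of freedom, integrated by seeded
#' quasi-Monte-Carlo. The adjusted p-value of contrast j is
#' `1 - P(max_i |T_i| <= |t_j|)`, which reduces to the unadjusted
#' two-sided p when there is a single treatment.
#'
#' @param fit a [fit_region_nbglm()] result.
#' @param seed integer seed for the multivariate-t integration.
#' @param dispersion_correction apply the Pearson-dispersion inflation
#'   (default `TRUE`; turn off to reproduce raw Wald statistics).
#' @return data.frame with one row per region x treatment: `region_id`,
#'   `group`, `log2fc`, `se_log2fc`, `statistic`, `df`, `p`, `p_dunnett`.
#' @export
dunnett_adjust <- function(fit, seed = 1, dispersion_correction = TRUE) {
  trt <- setdiff(fit$groups, fit$control)
  if (!length(trt)) stop("no treatment groups")
  rows <- list()
  for (r in names(fit$fits)) {
    f <- fit$fits[[r]]
    if (is.null(f)) {
      rows[[r]] <- data.frame(region_id = as.integer(r), group = trt,
                              log2fc = NA_real_, se_log2fc = NA_real_,
                              statistic = NA_real_, df = NA_real_,
                              p = NA_real_, p_dunnett = NA_real_)
      next
    }
    cn <- paste0("group", trt)
    est <- coef(f)[cn]
    V <- vcov(f)[cn, cn, drop = FALSE]
    df <- df.residual(f)
    # quasi-likelihood small-sample correction: inflate the Wald
    # covariance by the Pearson dispersion (floored at 1) — the ML theta
    # underestimates dispersion at few animals per group, making raw Wald
    # statistics anti-conservative
    infl <- if (dispersion_correction) {
      max(1, sum(residuals(f, type = "pearson")^2) / df)
    } else 1
    se <- sqrt(diag(V) * infl)
    z <- est / se
    R <- stats::cov2cor(V)
    p_raw <- 2 * pt(-abs(z), df)
    p_adj <- vapply(abs(z), function(q) {
      if (!is.finite(q)) return(NA_real_)
      pr <- with_seed(seed + as.integer(r) %% 10000L,
                      mvtnorm::pmvt(lower = rep(-q, length(z)),
                                    upper = rep(q, length(z)),
                                    df = as.integer(df), corr = R))
      max(1 - as.numeric(pr), 0)
    }, 0)
    p_adj <- pmax(p_adj, p_raw)  # adjustment contract: adjusted >= raw
    rows[[r]] <- data.frame(region_id = as.integer(r), group = trt,
                            log2fc = unname(est) / log(2),
                            se_log2fc = unname(se) / log(2),
                            statistic = unname(z), df = df,
                            p = unname(p_raw), p_dunnett = unname(p_adj))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment across regions within one comparison, capped at
#' 1 and monotone in the order statistics.
#'
#' @param pvalues numeric vector in `[0, 1]` (NAs pass through).
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Model diagnostics per region
#'
#' Screens every fitted region model: deviance residuals for gross
#' violations of normality (Shapiro screen at `resid_alpha`), Cook's
#' distance per observation (influential when above `cook_multiplier / n`),
#' and the low-count rule (any group's mean count below
#' `low_count_threshold` is considered too low to judge). Flagged regions
#' are reported, never dropped.
#'
#' @param fit a [fit_region_nbglm()] result.
#' @param low_count_threshold mean-count threshold (default 10).
#' @param cook_multiplier numerator of the Cook's distance cut-off.
#' @param resid_alpha significance level of the residual normality screen.
#' @return data.frame per region: `region_id`, `low_count`,
#'   `influential_points`, `residual_violation`, `max_cook`,
#'   `n_influential`.
#' @export
glm_diagnostics <- function(fit, low_count_threshold = 10,
                            cook_multiplier = 4, resid_alpha = 0.01) {
  rows <- lapply(names(fit$fits), function(r) {
    sub <- fit$counts[fit$counts$region_id == as.integer(r), ]
    gm <- tapply(sub$count, sub$group, mean)
    low <- any(gm < low_count_threshold)
    f <- fit$fits[[r]]
    if (is.null(f))
      return(data.frame(region_id = as.integer(r), low_count = low,
                        influential_points = NA, residual_violation = NA,
                        max_cook = NA_real_, n_influential = NA_integer_))
    cd <- cooks.distance(f)
    thr <- cook_multiplier / length(cd)
    infl <- cd > thr
    dr <- residuals(f, type = "deviance")
    rv <- FALSE
    if (length(dr) >= 3 && sd(dr) > 0)
      rv <- tryCatch(shapiro.test(dr)$p.value < resid_alpha,
                     error = function(e) FALSE)
    data.frame(region_id = as.integer(r), low_count = low,
               influential_points = any(infl), residual_violation = rv,
               max_cook = max(cd), n_influential = sum(infl))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

region_adjacency <- function(labels) {
  lab <- labels$labels
  pairs <- list()
  d <- dim(lab)
  shift_pairs <- function(a, b) {
    sel <- a != b & a > 0L & b > 0L
    unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
  }
  p1 <- shift_pairs(lab[-1, , , drop = FALSE], lab[-d[1], , , drop = FALSE])
  p2 <- shift_pairs(lab[, -1, , drop = FALSE], lab[, -d[2], , drop = FALSE])
  p3 <- shift_pairs(lab[, , -1, drop = FALSE], lab[, , -d[3], drop = FALSE])
  unique(rbind(p1, p2, p3))
}

#' Per-region statistics pipeline
#'
#' The full statistical chain for one study: per-region NB GLMs
#' ([fit_region_nbglm()]), Dunnett many-to-one contrasts within each model
#' ([dunnett_adjust()]), then BH-FDR across regions within each treatment
#' comparison, plus diagnostics ([glm_diagnostics()]). When a label volume
#' is supplied, a spillover-candidate column marks regions adjacent to a
#' region with at least `spillover_ratio` times their count density — an
#' aid for the manual visual check; it never alters significance.
#'
#' @param counts count data.frame (leaf- or analysis-level).
#' @param control name of the control group.
#' @param seed seed for the Dunnett integration.
#' @param labels optional [label_volume()] for the spillover heuristic.
#' @param spillover_ratio density ratio defining a high-signal neighbour.
#' @param ... passed to [glm_diagnostics()].
#' @return A `fos_region_stats` data.frame: one row per region x
#'   treatment with `log2fc`, `p`, `p_dunnett`, `p_fdr`, `dispersion` and
#'   diagnostic flags.
#' @export
region_stats <- function(counts, control, seed = 1, labels = NULL,
                         spillover_ratio = 10, ...) {
  fit <- fit_region_nbglm(counts, control)
  dn <- dunnett_adjust(fit, seed = seed)
  dn$p_fdr <- NA_real_
  for (g in unique(dn$group)) {
    sel <- dn$group == g
    dn$p_fdr[sel] <- bh_fdr(dn$p_dunnett[sel])
  }
  diag <- glm_diagnostics(fit, ...)
  theta <- vapply(fit$fits, function(f) if (is.null(f)) NA_real_ else f$theta, 0)
  dn$dispersion <- theta[as.character(dn$region_id)]
  out <- merge(dn, diag, by = "region_id", sort = TRUE)
  if (!is.null(labels)) {
    adj <- region_adjacency(labels)
    vox <- table(factor(labels$labels[labels$labels > 0L]))
    dens <- tapply(counts$count, counts$region_id, mean)
    dens <- dens / as.numeric(vox[names(dens)])
    out$spillover_candidate <- vapply(out$region_id, function(r) {
      nb <- c(adj[adj[, 1] == r, 2], adj[adj[, 2] == r, 1])
      if (!length(nb)) return(FALSE)
      dr <- dens[as.character(r)]
      any(dens[as.character(nb)] >= spillover_ratio * dr, na.rm = TRUE)
    }, TRUE)
  } else out$spillover_candidate <- NA
  class(out) <- c("fos_region_stats", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' @export
print.fos_region_stats <- function(x, alpha = 0.05, ...) {
  cat(sprintf("<fos_region_stats> %d regions x %d comparison(s); %d significant at FDR %.2g\n",
              length(unique(x$region_id)), length(unique(x$group)),
              sum(x$p_fdr < alpha, na.rm = TRUE), alpha))
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
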