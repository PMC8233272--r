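make_design <- function(n_per = 6, groups = c("vehicle", "treated")) {
  data.frame(animal_id = sprintf("m%02d", seq_len(n_per * length(groups))),
             group = rep(groups, each = n_per))
}

test_that("NB fits recover simulated effects and dispersion behaviour", {
  design <- make_design()
  # moderate replicate run; the full 200-replicate calibration lives in
  # the acceptance suite
  est <- vapply(1:60, function(i) {
    ct <- simulate_counts(1L, design, baseline_mean = 100,
                          log2fc_map = c(treated = 1), dispersion = 5,
                          seed = 500 + i)
    coef(fit_region_nbglm(ct, "vehicle"))[1, "treated"]
  }, 0)
  expect_lt(abs(mean(est) - 1), 0.15)
  # near-Poisson data: fitted mean-variance ratio close to 1
  ct <- simulate_counts(1:30, design, baseline_mean = 50, dispersion = 1e6,
                        seed = 77)
  fit <- fit_region_nbglm(ct, "vehicle")
  # fitted variance/mean ratio: 1 + mu/theta, averaged over fitted regions
  ok <- !vapply(fit$fits, is.null, TRUE)
  vm <- mean(vapply(fit$fits[ok], function(f) 1 + mean(fitted(f)) / f$theta, 0))
  expect_gt(vm, 0.8); expect_lt(vm, 1.2)
})

test_that("all-zero regions are flagged, not fitted", {
  design <- make_design(3)
  ct <- simulate_counts(1:2, design, baseline_mean = 20, seed = 5)
  ct$count[ct$region_id == 2] <- 0L
  fit <- fit_region_nbglm(ct, "vehicle")
  expect_equal(unname(fit$status[["2"]]), "all_zero")
  expect_null(fit$fits[["2"]])
  dn <- dunnett_adjust(fit)
  expect_true(is.na(dn$p[dn$region_id == 2]))
})

test_that("Dunnett with one treatment equals the unadjusted two-sided p", {
  design <- make_design()
  ct <- simulate_counts(1:5, design, baseline_mean = 80, dispersion = 4,
                        seed = 9)
  fit <- fit_region_nbglm(ct, "vehicle")
  dn <- dunnett_adjust(fit, seed = 3)
  expect_equal(dn$p_dunnett, dn$p, tolerance = 1e-3)
  expect_true(all(dn$p_dunnett >= dn$p - 1e-12))
})

test_that("Dunnett adjustment exceeds raw p and matches multcomp", {
  skip_if_not_installed("multcomp")
  design <- make_design(6, c("vehicle", "t1", "t2", "t3"))
  ct <- simulate_counts(1:4, design, baseline_mean = 60, dispersion = 6,
                        seed = 11)
  fit <- fit_region_nbglm(ct, "vehicle")
  expect_true(with(dunnett_adjust(fit, seed = 4),
                   all(p_dunnett >= p - 1e-12)))
  # cross-check the joint integration against the independent multcomp
  # implementation on the same (uncorrected) Wald statistics
  dn <- dunnett_adjust(fit, seed = 4, dispersion_correction = FALSE)
  expect_true(all(dn$p_dunnett >= dn$p - 1e-12))
  sub <- ct[ct$region_id == 1, ]
  sub$group <- relevel(factor(sub$group), "vehicle")
  f <- MASS::glm.nb(count ~ group, data = sub)
  gl <- summary(multcomp::glht(f, linfct = multcomp::mcp(group = "Dunnett")))
  ours <- dn$p_dunnett[dn$region_id == 1]
  ref <- as.numeric(gl$test$pvalues)
  trt <- sub("group", "", names(coef(f))[-1])
  ref_names <- sub(" - vehicle", "", rownames(gl$linfct))
  # multcomp integrates a multivariate normal, ours a multivariate t with
  # the residual df; agreement is approximate but must be close
  expect_equal(ours[match(ref_names, dn$group[dn$region_id == 1])], ref,
               tolerance = 0.06)
})

test_that("BH adjustment reproduces the step-up closed form and oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  set.seed(21)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("diagnostics flag influence, residual violations and low counts", {
  design <- make_design()
  ct <- simulate_counts(1L, design, baseline_mean = 100, dispersion = 10,
                        seed = 31)
  # implant one gross outlier: 50x the group mean
  i <- which(ct$group == "treated")[1]
  ct$count[i] <- as.integer(50 * mean(ct$count[ct$group == "treated"]))
  fit <- fit_region_nbglm(ct, "vehicle")
  dg <- glm_diagnostics(fit)
  expect_true(dg$influential_points[1])
  cd <- cooks.distance(fit$fits[[1]])
  expect_equal(unname(which.max(cd)), which(ct$region_id == 1)[i])
  # low-count rule: group means {4, 12} trip the threshold of 10
  ct2 <- data.frame(animal_id = rep(sprintf("m%d", 1:8)),
                    group = rep(c("vehicle", "treated"), each = 4),
                    region_id = 1L,
                    count = c(4L, 4L, 4L, 4L, 12L, 12L, 12L, 12L))
  dg2 <- glm_diagnostics(fit_region_nbglm(ct2, "vehicle"))
  expect_true(dg2$low_count[1])
  ct3 <- ct2; ct3$count <- rep(c(14L, 12L), each = 4)
  dg3 <- glm_diagnostics(fit_region_nbglm(ct3, "vehicle"))
  expect_false(dg3$low_count[1])
})

test_that("Cook flags stay calibrated on clean null data", {
  design <- make_design()
  frac <- vapply(1:40, function(i) {
    ct <- simulate_counts(1L, design, baseline_mean = 100, dispersion = 10,
                          seed = 900 + i)
    fit <- fit_region_nbglm(ct, "vehicle")
    dg <- glm_diagnostics(fit)
    dg$n_influential[1] / 12
  }, 0)
  expect_lte(mean(frac), 0.10)
})

test_that("the full pipeline is deterministic and FDR-monotone", {
  design <- make_design()
  ct <- simulate_counts(1:12, design, baseline_mean = 50,
                        log2fc_map = c(treated = 0.8), dispersion = 5,
                        seed = 41)
  r1 <- region_stats(ct, control = "vehicle", seed = 7)
  r2 <- region_stats(ct, control = "vehicle", seed = 7)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_true(all(r1$p_fdr >= r1$p_dunnett - 1e-12, na.rm = TRUE))
  expect_true(all(c("low_count", "influential_points", "residual_violation")
                  %in% names(r1)))
})

test_that("counts collapse before fitting conserves totals through the pipeline", {
  sa <- synthetic_atlas_ontology(12, 6)
  design <- make_design(3)
  leaves <- sa$ontology$region_id[sa$ontology$is_leaf]
  ct <- simulate_counts(leaves, design, baseline_mean = 30, seed = 51)
  cc <- collapse_to_parents(ct, sa$ontology, sa$level_map)
  expect_identical(sum(cc$count), sum(ct$count))
  expect_equal(length(unique(cc$region_id)), 6)
  res <- region_stats(cc, control = "vehicle")
  expect_equal(length(unique(res$region_id)), 6)
})
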