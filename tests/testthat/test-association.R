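test_that("BH q-values match the step-up closed form", {
  set.seed(19)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("guild-treatment model recovers planted effect signs with donor adjustment", {
  sim <- simulate_community(default_paper_scenario(seed = 23))
  rel <- to_relative(rarefy(sim$counts, 28000, seed = 24))
  gt <- aggregate_guilds(rel, sim$truth$feature_guild)
  tab <- fit_guild_treatment(gt, sim$metadata)
  expect_true(all(tab$q >= tab$p - 1e-12, na.rm = TRUE))
  row <- function(g, t) tab[tab$guild == g & tab$treatment == t, ]
  # reference is the no-oxygen, no-fiber arm
  expect_false("Control" %in% tab$treatment)
  p1 <- row("pathobiont_primary", "Oxygen")
  expect_gt(p1$coefficient, 0); expect_lt(p1$q, 0.05)
  p2 <- row("pathobiont_primary", "OxygenFiber")
  expect_lt(p2$coefficient, 0); expect_lt(p2$q, 0.05)
  f1 <- row("fermenter_a", "Oxygen")
  expect_lt(f1$coefficient, 0); expect_lt(f1$q, 0.05)
  expect_gt(row("fermenter_a", "OxygenFiber")$coefficient, 0)
  expect_gt(row("transitional", "OxygenFiber")$coefficient, 0)
})

test_that("a zero-variance guild is flagged and excluded from the FDR family", {
  meta <- null_design()
  set.seed(25)
  gt <- cbind(g1 = rep(0.3, nrow(meta)), g2 = runif(nrow(meta), 0.1, 0.5))
  rownames(gt) <- meta$sample_id
  tab <- fit_guild_treatment(gt, meta)
  expect_true(all(tab$flagged[tab$guild == "g1"]))
  expect_true(all(is.na(tab$q[tab$guild == "g1"])))
  expect_false(any(is.na(tab$q[tab$guild == "g2"])))
})

test_that("null guilds have uniform treatment p-values", {
  meta <- null_design()
  set.seed(26)
  donor_shift <- c(d1 = 0.5, d2 = -0.2, d3 = 0)
  p <- vapply(seq_len(200), function(i) {
    gt <- matrix(exp(rnorm(nrow(meta), donor_shift[meta$donor], 0.6)),
                 dimnames = list(meta$sample_id, "g"))
    fit_guild_treatment(gt, meta)$p[1]  # Oxygen term
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("standardized SCFA coefficients are unit-invariant and recover coupling", {
  sim <- simulate_community(default_paper_scenario(seed = 27))
  rel <- to_relative(rarefy(sim$counts, 28000, seed = 28))
  gt <- aggregate_guilds(rel, sim$truth$feature_guild)
  tab <- fit_guild_scfa(gt, sim$chem, sim$metadata)
  ferm <- tab[tab$guild == "fermenter_a" & tab$scfa == "acetate", ]
  expect_gt(ferm$std_coefficient, 0)
  expect_lt(ferm$q, 0.05)
  # doubling the SCFA units leaves the standardized coefficient unchanged
  chem2 <- sim$chem
  chem2$acetate <- chem2$acetate * 2
  tab2 <- fit_guild_scfa(gt, chem2, sim$metadata)
  expect_equal(tab2$std_coefficient[tab2$scfa == "acetate"],
               tab$std_coefficient[tab$scfa == "acetate"], tolerance = 1e-8)
  chem3 <- sim$chem
  chem3$butyrate <- 5
  expect_error(fit_guild_scfa(gt, chem3, sim$metadata), "constant SCFA")
})

test_that("mixed and donor-fixed fits agree in sign on a balanced design", {
  sim <- simulate_community(small_scenario(seed = 29))
  rel <- to_relative(sim$counts)
  gt <- aggregate_guilds(rel, sim$truth$feature_guild)
  meta <- sim$metadata
  logs <- log_transform(gt)
  keep <- meta$time_h > 0
  mixed <- fit_guild_treatment(gt, meta)
  for (g in colnames(gt)) {
    y <- logs[keep, g]
    lf <- lm(y ~ treatment + donor,
             data = data.frame(treatment = relevel(meta$treatment[keep], "Control"),
                               donor = meta$donor[keep]))
    cf <- coef(lf)[paste0("treatment", c("Oxygen", "Fiber", "OxygenFiber"))]
    got <- mixed$coefficient[mixed$guild == g][match(c("Oxygen", "Fiber", "OxygenFiber"),
                                                    mixed$treatment[mixed$guild == g])]
    expect_equal(sign(got), unname(sign(cf)))
  }
})

test_that("chemistry mixed model yields all Tukey contrasts and detects the fiber pH drop", {
  sim <- simulate_community(default_paper_scenario(seed = 33))
  ct <- fit_chem_treatment(sim$chem, sim$metadata, response = "pH")
  expect_equal(nrow(ct), choose(4, 2))
  fvc <- ct[ct$contrast == "Control - Fiber", ]
  expect_gt(fvc$estimate, 0)           # fiber acidifies
  expect_lt(fvc$p_tukey, 0.001)
  ac <- fit_chem_treatment(sim$chem, sim$metadata, response = "acetate")
  expect_lt(ac[ac$contrast == "Control - Fiber", "estimate"], 0)
  # single-donor designs fall back to fixed effects with a warning
  one <- sim$metadata$donor == "D1"
  expect_warning(
    fit_chem_treatment(sim$chem[one, ], sim$metadata[one, ], response = "pH"),
    "fixed-effects")
})

test_that("Tukey adjustment controls family-wise error on null chemistry", {
  meta <- null_design(n_rep = 3)
  set.seed(35)
  donor_shift <- c(d1 = 0.4, d2 = -0.4, d3 = 0)
  hit <- vapply(seq_len(500), function(i) {
    chem <- data.frame(sample_id = meta$sample_id,
                       pH = 6 + donor_shift[meta$donor] + rnorm(nrow(meta), 0, 0.3),
                       acetate = 1, propionate = 1, butyrate = 1)
    chem$acetate <- runif(nrow(meta))  # keep columns non-constant
    ct <- fit_chem_treatment(chem, meta, response = "pH")
    any(ct$p_tukey < 0.05)
  }, logical(1))
  expect_lte(mean(hit), 0.07)
})
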