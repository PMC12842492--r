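# a tiny 3-residue protein with well separated residues for region tests
region_fixture <- function() {
  at <- tibble::tibble(
    serial = 1:3, name = "CA", element = "C",
    x = c(0, 30, 60), y = 0, z = 0,
    chain = "A", resid = 1:3, icode = "", resname = "ALA",
    class = "polar_other")
  m <- linkerdock:::new_protein_model(at, model_id = "regions")
  rg <- regions_from_spans(list(linker = "A:1", pocket = "A:2"))
  list(model = m, regions = rg)
}

lig_at <- function(x, y = 0) {
  tibble::tibble(serial = 1L, name = "C1", element = "C", x = x, y = y,
                 z = 0, class = "hydrophobic")
}

test_that("region categories resolve per the pocket/linker/bridging rules", {
  fx <- region_fixture()
  # far from everything annotated
  expect_equal(assign_region(lig_at(200), fx$model, fx$regions)$category,
               "nonspecific")
  # touching linker residue only
  expect_equal(assign_region(lig_at(2), fx$model, fx$regions)$category,
               "linker")
  # touching pocket residue only
  expect_equal(assign_region(lig_at(28), fx$model, fx$regions)$category,
               "pocket")
  # a two-atom ligand contacting both linker and pocket bridges them
  bridge <- tibble::tibble(
    serial = 1:2, name = c("C1", "C2"), element = "C",
    x = c(2, 28), y = 0, z = 0, class = "hydrophobic")
  lab <- assign_region(bridge, fx$model, fx$regions)
  expect_equal(lab$category, "bridging")
  expect_setequal(lab$regions_touched, c("linker", "pocket"))
  expect_error(assign_region(lig_at(0), fx$model,
                             fx$regions[integer(0), ]), "empty")
})

test_that("a ligand H-bond-bridging linker and pocket residues is bridging", {
  # two serine-like anchors 7 A apart, annotated to different regions, with
  # a hydroxyl ligand within H-bond contact of both
  at <- tibble::tibble(
    serial = 1:2, name = "OG", element = "O", x = c(0, 7), y = 0, z = 0,
    chain = "A", resid = 1:2, icode = "", resname = "SER",
    class = "donor_acceptor")
  m <- linkerdock:::new_protein_model(at, model_id = "bridge")
  rg <- regions_from_spans(list(linker = "A:1", pocket = "A:2"))
  lig <- tibble::tibble(serial = 1L, name = "O1", element = "O",
                        x = 3.5, y = 0, z = 0, class = "donor_acceptor")
  expect_equal(assign_region(lig, m, rg)$category, "bridging")
})

test_that("background statistics use the sample SD over nonspecific records", {
  recs <- tibble::tibble(
    model_id = "m1", ligand_species = "glc",
    delta_g = c(-4.0, -5.0, -9.9, -9.8),
    category = c("nonspecific", "nonspecific", "linker", "pocket"))
  bg <- compute_background(recs)
  expect_equal(bg$mean, -4.5)
  expect_equal(bg$sd, sqrt(0.5), tolerance = 1e-12)   # 0.7071
  expect_equal(bg$n, 2)
  expect_error(compute_background(recs[3:4, ]), "at least 2")

  # parameter recovery from the synthetic generator at n = 10000
  tab <- make_dg_table(dg_table_spec(background_mean = -4.5,
                                     background_sd = 0.25,
                                     n_background = 10000, seed = 8)) |>
    dplyr::mutate(category = "nonspecific")
  bg2 <- compute_background(tab)
  expect_lt(abs(bg2$mean - (-4.5)), 0.01)
  expect_lt(abs(bg2$sd - 0.25), 0.01)
})

test_that("3-SD significance flags follow the strength axis, inclusive", {
  bg <- structure(list(mean = -4.46, sd = 0.25, n = 20,
                       ligand_species = "glc"), class = "dg_background")
  # cutoff = -4.46 - 0.75 = -5.21
  expect_true(flag_significant(-5.30, bg))
  expect_false(flag_significant(-5.10, bg))
  expect_true(flag_significant(-5.21, bg))              # boundary inclusive
  # monotone: anything stronger than a flagged value is flagged
  set.seed(2)
  dgs <- sort(rnorm(50, -5, 1))
  flags <- flag_significant(dgs, bg)
  expect_true(all(diff(as.integer(flags)) <= 0))
  # degenerate zero-SD background flags only strictly stronger energies
  bg0 <- structure(list(mean = -4, sd = 0, n = 5, ligand_species = "x"),
                   class = "dg_background")
  expect_false(flag_significant(-4, bg0))
  expect_true(flag_significant(-4.01, bg0))
})

test_that("planted outliers are recovered with a clean background", {
  spec <- dg_table_spec(
    background_mean = -4.5, background_sd = 0.25, n_background = 200,
    seed = 17,
    planted = lapply(1:5, function(i) {
      list(region = "linker", delta_g = -4.5 - (4 + i / 10) * 0.25,
           round = i, model_id = "mP")
    }))
  tab <- make_dg_table(spec) |>
    dplyr::mutate(category = ifelse(region == "other", "nonspecific",
                                    region))
  bg <- compute_background(tab)
  planted <- tab$category == "linker"
  flags <- flag_significant(tab$delta_g, bg)
  expect_equal(sum(flags[planted]), 5)                  # sensitivity 1.0
  expect_lte(mean(flags[!planted]), 0.01)               # background FPR
})

test_that("occupancy summaries match closed forms and hand counts", {
  recs <- tibble::tibble(
    model_id = rep(c("m1", "m2"), each = 10),
    delta_g = -5,
    category = c(rep("linker", 10),
                 c(rep("linker", 4), rep("nonspecific", 6))))
  # all 10 linker in m1, 4 in m2 -> {10, 4}
  occ <- occupancy_summary(recs, "linker")
  expect_equal(occ$mean_count, 7)
  expect_equal(occ$sd_count, sd(c(10, 4)))
  expect_equal(occ$n_models, 2)
  # counts {4, 6} closed form
  recs2 <- tibble::tibble(
    model_id = rep(c("m1", "m2"), each = 10),
    delta_g = -5,
    category = c(rep(c("linker", "nonspecific"), c(4, 6)),
                 rep(c("linker", "nonspecific"), c(6, 4))))
  occ2 <- occupancy_summary(recs2, "linker")
  expect_equal(occ2$mean_count, 5)
  expect_equal(occ2$sd_count, sqrt(2), tolerance = 1e-9)  # 1.414
  # bridging counts toward linker occupancy
  recs3 <- recs2
  recs3$category[recs3$category == "linker"] <- "bridging"
  expect_equal(occupancy_summary(recs3, "linker")$mean_count, 5)
  expect_equal(occupancy_summary(recs3, "pocket")$mean_count, 0)
})

test_that("Mann-Whitney exact p matches full enumeration", {
  r <- mann_whitney(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1/3, tolerance = 1e-12)
  # identical samples: no evidence of shift
  expect_gte(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)

  # oracle equivalence over random groups up to 6+6, including ties
  set.seed(5)
  for (rep in 1:10) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- round(rnorm(n1 + n2), 1)        # rounding induces ties
    a <- vals[1:n1]; b <- vals[(n1 + 1):(n1 + n2)]
    got <- mann_whitney(a, b, mode = "exact")
    # independent enumeration oracle
    pooled <- c(a, b)
    r <- rank(pooled)
    labelings <- combn(n1 + n2, n1)
    u_all <- apply(labelings, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
    u_obs <- sum(r[1:n1]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p_oracle <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    expect_identical(got$p_value, p_oracle)
    expect_identical(got$statistic, u_obs)
  }
  expect_error(mann_whitney(numeric(0), 1), "empty")
  expect_error(mann_whitney(1:7, 1:7, mode = "exact"), "<= 12")
})

test_that("the normal approximation tracks the reference implementation", {
  set.seed(9)
  a <- rnorm(30, 0); b <- rnorm(25, 0.8)
  got <- mann_whitney(a, b, mode = "normal_approx")
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-6)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("normality testing calibrates on known distributions", {
  set.seed(4)
  gauss <- rnorm(500)
  expect_gt(normality_test(gauss)$p_value, 0.01)
  expo <- rexp(500)
  expect_lt(normality_test(expo)$p_value, 0.01)
  expect_error(normality_test(c(1, 2)), "at least 3")
  expect_error(normality_test(rep(1, 10)), "identical")
})

test_that("heat-map tables carry round rows, time columns and flags", {
  recs <- tibble::tibble(
    model_id = rep(c("m1", "m2"), each = 3),
    time_label_ns = rep(c(10, 20), each = 3),
    ligand_species = "glc",
    round = rep(1:3, 2),
    delta_g = c(-4.4, -4.6, -6.5, -4.5, -4.4, -4.6),
    category = c("nonspecific", "nonspecific", "linker",
                 "nonspecific", "nonspecific", "nonspecific"))
  hm <- heatmap_table(recs)
  expect_equal(names(hm), c("round", "t10", "t20"))
  expect_equal(nrow(hm), 3)
  expect_match(hm$t10[3], "linker")
  expect_match(hm$t10[3], "\\*")            # far below bg mean - 3 sd
})
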