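test_that("CTI and CTV match their definitions and brute-force oracles", {
  expect_equal(compute_cti(3.0), 3.0)
  expect_equal(compute_cti(c(2, 4)), 3.0)
  expect_true(is.na(compute_cti(numeric(0))))

  expect_equal(compute_ctv(c(3, 3, 3)), 0)
  expect_equal(compute_ctv(c(2, 4)), sqrt(2))
  expect_true(is.na(compute_ctv(5)))

  set.seed(101)
  stis <- runif(50, 1, 5)
  expect_equal(compute_cti(stis), sum(stis) / 50, tolerance = 1e-12)
  expect_equal(compute_ctv(stis), two_pass_sd(stis), tolerance = 1e-12)
})

test_that("a priori exclusions remove exactly the listed species", {
  pool <- generate_species_pool(30, c(7, 16), seed = 111)
  sc <- shift_scenario(n_squares = 25, seed = 112)
  ds <- generate_surveys(pool, sc)
  target <- names(sort(table(ds$occurrences$species_id), decreasing = TRUE))[1:3]
  n_target <- sum(ds$occurrences$species_id %in% target)
  expect_gt(n_target, 0)

  out <- apply_exclusions(ds, target)
  expect_equal(nrow(out$occurrences), nrow(ds$occurrences) - n_target)
  expect_false(any(out$occurrences$species_id %in% target))

  expect_identical(apply_exclusions(ds, character(0)), ds)
  expect_warning(apply_exclusions(ds, "no_such_species"), "absent")

  # excluding every species empties the communities; flagged via NA indices
  all_sp <- unique(ds$occurrences$species_id)
  empty <- apply_exclusions(ds, all_sp)
  idx <- index_table(empty, sti_table(pool), NULL)
  expect_true(all(is.na(idx$cti)))
})

test_that("index_table computes per-cell indices and enforces STI coverage", {
  squares <- data.frame(square_id = "s1", altitude_m = 700,
                        altitudinal_range_m = 120, year_survey1 = 2003,
                        year_survey2 = 2008, stringsAsFactors = FALSE)
  occ <- data.frame(
    square_id = "s1",
    survey = c(1, 1, 2, 2),
    year = c(2003, 2003, 2008, 2008),
    species_id = c("A", "B", "B", "C"),
    stringsAsFactors = FALSE)
  ds <- structure(list(occurrences = occ, squares = squares),
                  class = "survey_dataset")
  sti <- data.frame(species_id = c("A", "B", "C"), group = "g",
                    sti = c(2, 4, 5), stringsAsFactors = FALSE)
  idx <- index_table(ds, sti, "g")
  expect_equal(idx$cti[idx$survey == 1], 3.0)
  expect_equal(idx$cti[idx$survey == 2], 4.5)
  expect_equal(idx$richness, c(2L, 2L))

  # duplicated occurrence rows must not change the index (presence/absence)
  ds_dup <- ds
  ds_dup$occurrences <- rbind(occ, occ[1, ])
  expect_equal(index_table(ds_dup, sti, "g")$cti, idx$cti)

  # species missing from the STI table is a hard error naming the offender
  sti_short <- sti[sti$species_id != "C", ]
  expect_error(index_table(ds, sti_short, "g"), "C")
})

test_that("index table covers every square-survey cell on synthetic data", {
  pool <- butterfly_pool(121, n_species = 200)
  sc <- shift_scenario(n_squares = 40, seed = 122)
  ds <- generate_surveys(pool, sc)
  idx <- index_table(ds, sti_table(pool), NULL)
  expect_equal(nrow(idx), 2L * 40L)
  expect_false(any(is.na(idx$richness)))
  # CTI bounded by member STIs; CTV zero iff all members equal
  expect_true(all(idx$cti >= min(pool$sti) & idx$cti <= max(pool$sti),
                  na.rm = TRUE))
})

test_that("removing a warm species strictly lowers the CTI", {
  stis <- c(2.5, 3.1, 4.8, 3.9)
  cti <- compute_cti(stis)
  warm <- which(stis > cti)[1]
  expect_lt(compute_cti(stis[-warm]), cti)
})

test_that("cross-taxon correlation matches its t/df/p definition", {
  x <- 1:10
  y <- 2 * x + 1
  ct <- cross_taxon_correlation(x, y)
  expect_equal(ct$r, 1.0)
  expect_lt(ct$p, 1e-10)
  expect_equal(ct$df, 8L)

  # agreement with the standard test as an independent route
  set.seed(131)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  ct2 <- cross_taxon_correlation(a, b)
  ref <- cor.test(a, b)
  expect_equal(ct2$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ct2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ct2$p, ref$p.value, tolerance = 1e-12)

  # the monitoring design: 214 squares -> 212 degrees of freedom
  set.seed(132)
  u <- rnorm(214); v <- rnorm(214)
  expect_equal(cross_taxon_correlation(u, v)$df, 212L)

  # permutation null: p roughly uniform, |r| small
  set.seed(133)
  ps <- replicate(200, cross_taxon_correlation(u, sample(v))$p)
  expect_gt(min(ps), 0)
  expect_true(abs(mean(ps < 0.5) - 0.5) < 0.15)

  expect_warning(out <- cross_taxon_correlation(rep(1, 10), rnorm(10)),
                 "zero variance")
  expect_true(is.na(out$r))
})

test_that("coupled synthetic communities correlate across taxon groups", {
  sc <- shift_scenario(n_squares = 120, seed = 141)
  set.seed(141)
  squares <- thermocomm:::simulate_squares(sc)
  pools <- list(butterfly_pool(142, 300),
                generate_species_pool(300, c(1, 5), seed = 143))
  cti1 <- lapply(seq_along(pools), function(i) {
    sci <- sc; sci$seed <- 150 + i
    ds <- generate_surveys(pools[[i]], sci, squares = squares)
    idx <- index_table(ds, sti_table(pools[[i]]), NULL)
    s1 <- idx[idx$survey == 1, ]
    s1$cti[match(squares$square_id, s1$square_id)]
  })
  ct <- cross_taxon_correlation(cti1[[1]], cti1[[2]])
  expect_gt(ct$r, 0.5)
})
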