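# small labelled collection used across these tests
disc_fixture <- function(n_green = 3, n_brown = 3, seed = 5) {
  set.seed(seed)
  wl <- 300:700
  mk <- function(mu) gauss_refl(wl, mu, 30) + rnorm(401, 0, 0.2)
  cols <- c(lapply(seq_len(n_green), function(i) mk(540)),
            lapply(seq_len(n_brown), function(i) mk(600)))
  ids <- c(sprintf("g%d", seq_len(n_green)), sprintf("b%d", seq_len(n_brown)))
  refl <- do.call(cbind, cols); colnames(refl) <- ids
  meta <- data.frame(sample_id = ids,
                     morph = rep(c("green", "brown"), c(n_green, n_brown)),
                     patch = "dorsal", individual = ids)
  offset_nonnegative(spectra(wl, refl, meta))
}

test_that("duplicated groups give zero distance and no discriminability call", {
  x <- disc_fixture(1, 0)
  one <- x$refl[, 1]
  refl2 <- cbind(g1 = one, g2 = one, g3 = one,
                 copy1 = one, copy2 = one, copy3 = one)
  meta2 <- data.frame(sample_id = colnames(refl2),
                      morph = rep(c("green", "greencopy"), each = 3),
                      patch = "dorsal")
  x2 <- spectra(x$wl, refl2, meta2)
  for (m in c("pairwise_mean", "centroid")) {
    cmp <- compare_groups(x2, list(morph = "green"),
                          list(morph = "greencopy"),
                          builtin_systems()$lizard, method = m)
    expect_equal(cmp$dS_mean, 0, tolerance = 1e-9)
    expect_equal(cmp$dL_mean, 0, tolerance = 1e-9)
    expect_false(cmp$discriminable)
  }
  # duplicated but internally heterogeneous groups: the centroid method is
  # still exactly zero, the pairwise mean only for the matching pairs
  y <- disc_fixture(3, 0)
  refl3 <- cbind(y$refl, copy1 = y$refl[, 1], copy2 = y$refl[, 2],
                 copy3 = y$refl[, 3])
  meta3 <- data.frame(sample_id = colnames(refl3),
                      morph = rep(c("green", "greencopy"), each = 3),
                      patch = "dorsal")
  y2 <- spectra(y$wl, refl3, meta3)
  ce <- compare_groups(y2, list(morph = "green"), list(morph = "greencopy"),
                       builtin_systems()$lizard, method = "centroid")
  expect_equal(ce$dS_mean, 0, tolerance = 1e-9)
  expect_equal(ce$dL_mean, 0, tolerance = 1e-9)
})

test_that("pair counts and singleton equivalences hold", {
  x <- disc_fixture(2, 3)
  sys <- builtin_systems()$bee
  cmp <- compare_groups(x, list(morph = "green"), list(morph = "brown"), sys)
  expect_equal(cmp$n_pairs, 6)

  x1 <- disc_fixture(1, 1)
  pm <- compare_groups(x1, list(morph = "green"), list(morph = "brown"), sys,
                       method = "pairwise_mean")
  ce <- compare_groups(x1, list(morph = "green"), list(morph = "brown"), sys,
                       method = "centroid")
  expect_equal(pm$dS_mean, ce$dS_mean)
  expect_equal(pm$dL_mean, ce$dL_mean)
  qc <- quantum_catch(x1, sys)
  pd <- pairwise_distances(qc, sys)
  expect_equal(pm$dS_mean, pd$dS)
  expect_equal(pm$dL_mean, pd$dL)
})

test_that("group comparison is symmetric in the group labels", {
  x <- disc_fixture(3, 4)
  sys <- builtin_systems()$starling
  for (m in c("pairwise_mean", "centroid")) {
    ab <- compare_groups(x, list(morph = "green"), list(morph = "brown"),
                         sys, method = m)
    ba <- compare_groups(x, list(morph = "brown"), list(morph = "green"),
                         sys, method = m)
    expect_equal(ab$dS_mean, ba$dS_mean)
    expect_equal(ab$dL_mean, ba$dL_mean)
    expect_equal(ab$n_pairs, ba$n_pairs)
  }
})

test_that("degenerate group selections are refused", {
  x <- disc_fixture()
  sys <- builtin_systems()$fly
  expect_error(compare_groups(x, list(morph = "blue"), list(morph = "brown"),
                              sys), "empty")
  expect_error(compare_groups(x, list(patch = "dorsal"),
                              list(morph = "brown"), sys), "overlap")
})

test_that("default plans match the published table structure", {
  expect_equal(nrow(default_plan("sibiricus")), 4)
  expect_equal(nrow(default_plan("dorsatus")), 10)
  expect_equal(nrow(default_plan()), 14)
  sp <- gen_morph_spectra(spectra_gen_config(
    species = list(
      sibiricus = list(n = c(green = 2, brown = 2), contrast = 0.5,
                       indiv_cv = 0.1),
      dorsatus = list(n = c(brown = 2, dorsal_green = 2, lateral_green = 2),
                      contrast = 0.5, indiv_cv = 0.1)),
    n_replicates = 1), seed = 2)
  sp <- offset_nonnegative(sp)
  tab <- run_comparison_table(sp)
  expect_equal(nrow(tab), (4 + 10) * 6)
  expect_equal(sum(tab$species == "sibiricus"), 4 * 6)
  expect_equal(sum(tab$species == "dorsatus"), 10 * 6)
  expect_equal(nrow(run_comparison_table(sp, plan = default_plan()[0, ])), 0)
  bad <- default_plan("sibiricus")
  bad$morph_a[1] <- "hawk"
  expect_error(run_comparison_table(sp, plan = bad), "hawk")
})

test_that("pied spectra are pooled with brown in the top-level fit", {
  sp <- gen_morph_spectra(spectra_gen_config(
    species = list(sibiricus = list(n = c(green = 3, pied = 3),
                                    contrast = 0.5, indiv_cv = 0.1)),
    n_replicates = 1), seed = 4)
  fit <- morph_discrimination(sp, systems = builtin_systems()["lizard"],
                              plan = default_plan("sibiricus"))
  # pied-only brown group still yields all four comparison rows
  expect_equal(nrow(fit$comparisons), 4)
  expect_true(all(fit$comparisons$n_pairs >= 1))
})

test_that("reports flag strict threshold exceedance and round-trip in JSON", {
  tab <- data.frame(species = "s", label = c("x", "y", "z"), system = "bee",
                    dS_mean = c(3.5, 3.0, 2.1), dL_mean = c(4, 2, 3.0001),
                    n_pairs = 1L, discriminable = c(TRUE, FALSE, FALSE))
  f <- withr::local_tempfile(fileext = ".json")
  render_report(tab, f, "json")
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$dS_flag, c(TRUE, FALSE, FALSE))
  expect_equal(back$dL_flag, c(TRUE, FALSE, TRUE))
  expect_equal(back$dS_mean, tab$dS_mean)
  expect_equal(back$dL_mean, tab$dL_mean)
  fmd <- withr::local_tempfile(fileext = ".md")
  render_report(tab, fmd, "markdown")
  lines <- readLines(fmd)
  expect_length(lines, 5)
  expect_match(lines[3], "\\*\\*3\\.5\\*\\*")
  expect_false(grepl("\\*\\*3\\*\\*", lines[4]))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  render_report(tab, fcsv, "csv")
  expect_equal(nrow(read.csv(fcsv)), 3)
  expect_error(render_report(tab, f, "xml"), "arg")
})
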