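test_that("proposed sites are placed uniformly over the positions range", {
  ctx <- tiny_context(n_sites = 10)
  expect_equal(ctx$proposed_sites, seq(0, 1, length.out = 10))

  # explicit proposals pass through verbatim
  scn <- simulation_scenario(seed = 2, n_selected = 30, n_neutral = 200)
  dat <- simulate_scenario(scn)
  cfg <- run_config(Ne = 1e4, rec = 0.005, selected_pops = c(1, 3, 5),
                    sel_sites = c(0.2, 0.6), num_bins = 50,
                    sels = 0.05, migs = 0.1, times = 0, gs = 0.01,
                    sources = 1)
  ctx2 <- suppressMessages(build_context(dat$neutral, dat$selected, cfg))
  expect_equal(ctx2$proposed_sites, c(0.2, 0.6))

  cfg_bad <- run_config(Ne = 1e4, rec = 0.005, selected_pops = c(1, 3, 5),
                        n_sites = 1000, num_bins = 50, sels = 0.05,
                        migs = 0.1, times = 0, gs = 0.01, sources = 1)
  expect_error(
    suppressMessages(build_context(dat$neutral, dat$selected, cfg_bad)),
    "must be <="
  )
})

test_that("context construction is deterministic and idempotent", {
  a <- tiny_context(seed = 4)
  b <- tiny_context(seed = 4)
  expect_equal(a, b)
})

test_that("every mode returns the 10-column schema with correct row counts", {
  ctx <- tiny_context(sels = seq(0.01, 0.1, length.out = 23), n_sites = 10)
  n_site <- 10

  neut <- fit_mode(ctx, "neutral")
  ind <- fit_mode(ctx, "independent")
  expect_equal(nrow(neut), n_site)
  expect_equal(nrow(ind), n_site * 23)  # 10 proposed sites x 23 sels

  ctx2 <- tiny_context()  # 3 sels, 2 migs, 2 times, 2 gs, 3 sources, 4 sites
  mig <- fit_mode(ctx2, "migration")
  std <- fit_mode(ctx2, "standing")
  svs <- fit_mode(ctx2, "standing_source")
  expect_equal(nrow(mig), 4 * 3 * 2 * 3)
  expect_equal(nrow(std), 4 * 3 * 2 * 2)
  expect_equal(nrow(svs), 4 * 3 * 2 * 2 * 3)

  schema <- c("selected_sites", "sels", "migs", "times", "gs", "sources",
              "cle", "selected_pops", "locus_name", "model")
  for (res in list(neut, ind, mig, std, svs)) {
    expect_identical(names(res), schema)
  }

  # unused grid parameters are NA; used ones never are
  expect_true(all(is.na(ind$migs)) && all(is.na(ind$times)) &&
                all(is.na(ind$gs)) && all(is.na(ind$sources)))
  expect_false(anyNA(ind$sels))
  expect_true(all(is.na(mig$times)) && all(is.na(mig$gs)))
  expect_false(anyNA(mig$migs) || anyNA(mig$sources))
  expect_true(all(is.na(std$migs)) && all(is.na(std$sources)))
  expect_true(all(is.na(neut$sels)))

  expect_true(all(ind$selected_pops == "1-3-5"))
})

test_that("rows follow the nested grid order with sources innermost", {
  ctx <- tiny_context()
  svs <- fit_mode(ctx, "standing_source")
  n_inner <- nrow(svs) / length(ctx$proposed_sites)
  # outermost axis changes slowest
  expect_equal(svs$selected_sites,
               rep(ctx$proposed_sites, each = n_inner))
  # innermost axis cycles fastest
  expect_equal(svs$sources[seq_along(ctx$sources)], ctx$sources)
})

test_that("neutral fits replicate one composite likelihood across proposed sites", {
  ctx <- tiny_context()
  neut <- fit_mode(ctx, "neutral")
  expect_equal(length(unique(neut$cle)), 1L)
  expect_equal(nrow(neut), length(ctx$proposed_sites))
})

test_that("fits are pure functions of the context", {
  ctx <- tiny_context()
  expect_equal(fit_mode(ctx, "independent"), fit_mode(ctx, "independent"))
})

test_that("mode tables concatenate into one 10-column table", {
  ctx <- tiny_context()
  ctx <- update_mode(ctx, list(c(1, 3), 5), c("standing_source", "independent"))
  all_mods <- dplyr::bind_rows(
    fit_mode(ctx, "independent"),
    fit_mode(ctx, "migration"),
    fit_mode(ctx, "standing_source"),
    fit_mode(ctx, "multi")
  )
  expect_equal(ncol(all_mods), 10L)
  expect_equal(dplyr::n_distinct(all_mods$model), 4L)
})

test_that("mixed-mode fitting validates its partition and reuses precomputation", {
  ctx <- tiny_context()
  expect_error(fit_mode(ctx, "multi"), "update_mode")
  expect_error(update_mode(ctx, list(c(1, 3)), "independent"),
               "cover exactly selected_pops")
  expect_error(update_mode(ctx, list(c(1, 3), c(3, 5)),
                           c("independent", "independent")),
               "cover exactly selected_pops")
  expect_error(
    update_mode(ctx, list(c(1, 3), 5), c("migration", "standing_source")),
    "at most one set"
  )

  a <- update_mode(ctx, list(c(1, 3), 5), c("standing_source", "independent"))
  b <- update_mode(a, list(c(1, 5), 3), c("independent", "independent"))
  expect_equal(b$F, ctx$F)  # no re-estimation
  expect_equal(b$modes, c("independent", "independent"))  # last spec wins

  # the sources axis of a mixed fit is restricted to the source-requiring set
  mlt <- fit_mode(a, "multi")
  expect_true(all(mlt$sources %in% c(1, 3)))
})

test_that("a one-group mixed fit reproduces the single-mode fit", {
  ctx <- tiny_context()
  ctx1 <- update_mode(ctx, list(c(1, 3, 5)), "independent")
  mlt <- fit_mode(ctx1, "multi")
  ind <- fit_mode(ctx, "independent")
  expect_lt(max(abs(mlt$cle - ind$cle)), 1e-12)
})

test_that("MCLE extraction returns the best row with deterministic tie-breaks", {
  ctx <- tiny_context()
  ind <- fit_mode(ctx, "independent")
  best <- mcle_summary(ind)
  expect_equal(nrow(best), 1L)
  expect_equal(best$cle, max(ind$cle))

  # all-equal cle: first grid row wins
  tied <- ind
  tied$cle <- 1
  expect_equal(mcle_summary(tied)$selected_sites, ind$selected_sites[1])

  # tidy()/glance() expose the same estimates
  expect_equal(tidy(ind), best)
  g <- glance(ind)
  expect_equal(g$n_grid, nrow(ind))
  expect_equal(g$max_cle, max(ind$cle))
})

test_that("likelihood profiles are relative to neutral and warn on unused axes", {
  ctx <- tiny_context()
  neut <- fit_mode(ctx, "neutral")
  neut_cle <- unique(neut$cle)

  prof0 <- cle_profile(neut, neut_cle, "selected_sites")
  expect_true(all(prof0$mcle == 0))

  ind <- fit_mode(ctx, "independent")
  prof <- cle_profile(ind, neut_cle, "sels")
  expect_equal(nrow(prof), length(ctx$sels))
  expect_equal(max(prof$mcle), max(ind$cle) - neut_cle)

  expect_warning(cle_profile(ind, neut_cle, "migs"), "unused")

  p <- plot_profile(dplyr::bind_rows(ind, fit_mode(ctx, "migration")),
                    neut_cle, "selected_sites")
  expect_s3_class(p, "ggplot")
})
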