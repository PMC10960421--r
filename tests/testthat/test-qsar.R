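# committee-spread application on the substituted-quinone grid

fx_qsar_grid <- function() fx_get("qsar_grid", function() {
  enumerate_substituted()
})

test_that("the substitution grid has the expected size and flags clashes", {
  g <- fx_qsar_grid()
  # up to 2 hydroxyls x up to 2 methyls on 6 positions:
  # (1 + 6 + 15)^2 = 484 cells
  expect_equal(nrow(g), 484)
  # clashing placements (same position twice) are invalid with no structure
  clash <- g$hydroxyl != "" & g$methyl != "" &
    mapply(function(a, b) length(intersect(strsplit(a, ",")[[1]],
                                           strsplit(b, ",")[[1]])) > 0,
           g$hydroxyl, g$methyl)
  expect_true(all(is.na(g$smiles[clash])))
  expect_true(all(!g$valid[clash]))
  expect_equal(sum(g$valid & !g$duplicate), 283)
  # the unsubstituted template sits in the first cell and is valid
  expect_equal(g$row[1], "none")
  expect_true(g$valid[1])
})

test_that("an unparseable template is rejected", {
  expect_error(enumerate_substituted(template = "not-a-structure"),
               "unparseable template")
})

test_that("non-normalized spread equals twice the population standard deviation", {
  set.seed(31)
  x <- rnorm(11)
  expect_equal(nonnormalized_spread(x),
               2 * sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
  expect_equal(nonnormalized_spread(c(0.3, 0.3, 0.3)), 0)
  expect_error(nonnormalized_spread(0.5))
})

test_that("spread heatmaps score exactly the valid unique cells", {
  g <- fx_qsar_grid()
  committee <- toy_committee(g, seed = 2)
  hm <- spread_heatmap(g, committee)
  expect_s3_class(hm, "spread_heatmap")
  scored <- hm$valid & !hm$duplicate
  expect_true(all(is.finite(hm$spread[scored])))
  expect_true(all(is.na(hm$spread[!scored])))
  expect_true(all(hm$spread[scored] >= 0))
  # training members are flagged and the top list excludes them
  expect_equal(sum(hm$in_training),
               sum(hm$canonical %in% attr(committee, "training") & scored))
  top <- attr(hm, "top")
  expect_equal(nrow(top), 4)
  expect_true(all(!top$in_training))
  expect_equal(top$spread, sort(top$spread, decreasing = TRUE))
  expect_s3_class(autoplot(hm), "ggplot")
})

test_that("candidate ranking emits consistent high, low, and random batches", {
  g <- fx_qsar_grid()
  hm <- spread_heatmap(g, toy_committee(g, seed = 2))
  rk <- rank_training_candidates(hm, batch_size = 10, seed = 3)
  expect_equal(unname(table(rk$batch)[c("high", "low", "random")]),
               rep(10L, 3), ignore_attr = TRUE)
  hi <- rk[rk$batch == "high", ]
  lo <- rk[rk$batch == "low", ]
  expect_equal(hi$rank, 1:10)
  expect_true(min(lo$spread) <= min(hi$spread))
  expect_true(all(hi$spread >= lo$spread))
  # random batch is reproducible under the seed
  rk2 <- rank_training_candidates(hm, batch_size = 10, seed = 3)
  expect_identical(rk, rk2)
  expect_warning(rank_training_candidates(hm, batch_size = 1e5),
                 "batch_size exceeds")
})
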