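# Propagating oriented repeat copies through inversion scenarios.

toy_pair_config <- function(n = 6) {
  repeat_config(scperm(seq_len(n)), copies = list(
    list(label = "R#1", orient = "+", junction = 1L),
    list(label = "R#2", orient = "+", junction = 1L)))
}

test_that("inversions conserve copies and default slots leave junction copies put", {
  cfg <- toy_pair_config()
  out <- apply_inversion_traced(cfg, 2, 5)
  expect_identical(nrow(plastrearr:::config_copies(out)), 2L)
  expect_identical(classify_arrangement(out, "R"), "tandem_forward")
  # involution with default slots
  back <- apply_inversion_traced(out, 2, 5)
  expect_identical(back, cfg)
  expect_error(apply_inversion_traced(cfg, 1, 3, c(5, NA)), "slot")
})

test_that("a cut between tandem copies splits them into an inverted dispersed pair", {
  cfg <- toy_pair_config()
  out <- apply_inversion_traced(cfg, 1, 4, c(1L, NA))
  expect_identical(classify_arrangement(out, "R"), "dispersed_inverted")
  expect_identical(count_repeat_loci(out, "R"), 2L)
})

test_that("splitting theorem holds exhaustively on 6-8 block toys", {
  for (n in 6:8) {
    base <- toy_pair_config(n)
    for (i in 0:(n - 1)) for (j in (i + 1):n) {
      if (i == 0 && j == n) next
      ji <- if (i == 0) n else i
      si_opts <- if (ji == 1) 0:2 else NA
      sj_opts <- if (j == 1) 0:2 else NA
      for (si in si_opts) for (sj in sj_opts) {
        out <- apply_inversion_traced(base, i, j, c(si, sj))
        n_sep <- sum(c(!is.na(si) && si == 1 && ji == 1,
                       !is.na(sj) && sj == 1 && j == 1))
        cls <- classify_arrangement(out, "R")
        if (n_sep == 1) {
          expect_identical(cls, "dispersed_inverted")
          expect_identical(count_repeat_loci(out, "R"), 2L)
        } else {
          expect_identical(cls, "tandem_forward")
          expect_identical(count_repeat_loci(out, "R"), 1L)
        }
      }
    }
  }
})

test_that("scenarios trace stepwise, reverse cleanly, and conserve copy number", {
  cfg <- toy_pair_config(8)
  expect_identical(trace_scenario(cfg, list()), list(cfg))
  steps <- list(list(i = 2, j = 5), list(i = 3, j = 7), list(i = 1, j = 6))
  tr <- trace_scenario(cfg, steps)
  expect_length(tr, 4L)
  expect_identical(tr[[1]], cfg)
  for (st in tr)
    expect_identical(nrow(plastrearr:::config_copies(st)), 2L)
  # replaying the inverse scenario returns the initial configuration
  back <- trace_scenario(tr[[4]], rev(steps))
  expect_identical(back[[4]], cfg)
})

test_that("classification covers every arrangement class", {
  single <- repeat_config(scperm(1:4), copies = list(
    list(label = "R#1", orient = "+", junction = 2L)))
  expect_identical(classify_arrangement(single, "R"), "single")
  ai <- repeat_config(scperm(1:4), copies = list(
    list(label = "R#1", orient = "+", junction = 2L),
    list(label = "R#2", orient = "-", junction = 2L)))
  expect_identical(classify_arrangement(ai, "R"), "adjacent_inverted")
  df <- repeat_config(scperm(1:4), copies = list(
    list(label = "R#1", orient = "+", junction = 1L),
    list(label = "R#2", orient = "+", junction = 3L)))
  expect_identical(classify_arrangement(df, "R"), "dispersed_forward")
  di <- repeat_config(scperm(1:4), copies = list(
    list(label = "R#1", orient = "+", junction = 1L),
    list(label = "R#2", orient = "-", junction = 3L)))
  expect_identical(classify_arrangement(di, "R"), "dispersed_inverted")
  multi <- repeat_config(scperm(1:4), copies = list(
    list(label = "R#1", orient = "+", junction = 1L),
    list(label = "R#2", orient = "-", junction = 3L),
    list(label = "R#3", orient = "+", block = 2L)))
  cls <- classify_arrangement(multi, "R")
  expect_identical(as.character(cls), "multi_copy_mixed")
  expect_identical(nrow(attr(cls, "pairs")), 3L)
  expect_error(classify_arrangement(single, "Q"), "no copies")
})

test_that("the narrated tandem-to-sIR scenario reproduces the two-locus split", {
  tr <- trace_scenario(trnq_config_sciadopitys(), trnq_scenario_to_taxus())
  expect_length(tr, 3L)
  expect_identical(classify_arrangement(tr[[1]], "trnQ"), "tandem_forward")
  # after the first inversion the pair is still tandem, next to LCB 2
  expect_identical(classify_arrangement(tr[[2]], "trnQ"), "tandem_forward")
  fin <- tr[[3]]
  expect_identical(classify_arrangement(fin, "trnQ"), "dispersed_inverted")
  expect_identical(count_repeat_loci(fin, "trnQ"), 2L)
  nb <- plastrearr:::copy_neighbourhoods(fin, "trnQ")
  flanks <- lapply(nb, `[[`, "blocks")
  expect_true(any(vapply(flanks, function(b) 1 %in% b, logical(1))))  # psbK/psbI side
  expect_true(any(vapply(flanks, function(b) 2 %in% b, logical(1))))  # rps16/chlB side
})

test_that("the narrated three-copy scenario yields loci in LCB 2, 1 and 12", {
  tr <- trace_scenario(trnq_config_a25(), trnq_scenario_to_cunninghamia())
  fin <- tr[[length(tr)]]
  expect_identical(count_repeat_loci(fin, "trnQ"), 3L)
  orients <- copy_orientations(fin, "trnQ")
  expect_identical(sort(table(orients), decreasing = TRUE)[[1]], 2L)  # two same
  expect_identical(length(orients), 3L)
  cls <- classify_arrangement(fin, "trnQ")
  expect_identical(as.character(cls), "multi_copy_mixed")
  nb <- plastrearr:::copy_neighbourhoods(fin, "trnQ")
  expect_true(any(vapply(nb, function(x) x$kind == "internal" && x$blocks == 2,
                         logical(1))))                         # copy in LCB 2
  expect_true(any(vapply(nb, function(x) 1 %in% x$blocks, logical(1))))
  expect_true(any(vapply(nb, function(x) 12 %in% x$blocks, logical(1))))
})
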