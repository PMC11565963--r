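makeCounts <- function(reads_by_barcode, edit_of, neutral = character(),
                       T = 3L) {
  # reads_by_barcode: named list barcode -> per-timepoint reads
  rows <- do.call(rbind, lapply(names(reads_by_barcode), function(b)
    data.frame(barcode_id = b, edit_id = edit_of[[b]], replicate = "R1",
               condition = "1D", timepoint = seq_len(T) - 1L,
               reads = reads_by_barcode[[b]], stringsAsFactors = FALSE)))
  BarcodeExperiment(rows, neutralEdits = neutral)
}

test_that("outlier removal discards the highest-count barcode per edit", {
  be <- makeCounts(
    list(b1 = c(40, 30, 30), b2 = c(30, 30, 30), b3 = c(20, 30, 30),
         n1 = c(5, 5, 5)),
    list(b1 = "e1", b2 = "e1", b3 = "e1", n1 = "neutral_1"),
    neutral = "neutral_1")
  out <- removeOutlierBarcodes(be)
  rb <- removedBarcodes(out)
  expect_equal(rb$barcode_id, "b1")
  m <- SummarizedExperiment::assay(out, "counts")
  expect_true(all(is.na(m["b1", ])))
  expect_false(anyNA(m["b2", ]))
  # neutral anchor untouched
  expect_false(anyNA(m["n1", ]))
})

test_that("single-barcode edits are untouched and ties break lexicographically", {
  be <- makeCounts(
    list(solo = c(10, 10, 10),
         zb = c(50, 25, 25), za = c(25, 50, 25), zc = c(20, 20, 10),
         n1 = c(5, 5, 5)),
    list(solo = "e_solo", zb = "e2", za = "e2", zc = "e2",
         n1 = "neutral_1"),
    neutral = "neutral_1")
  out <- removeOutlierBarcodes(be)
  rb <- removedBarcodes(out)
  # za and zb tie at 100 total; lexicographically smallest id removed
  expect_equal(rb$barcode_id, "za")
  m <- SummarizedExperiment::assay(out, "counts")
  expect_false(anyNA(m["solo", ]))
})

test_that("per-stream removal can discard different barcodes per replicate", {
  rows <- rbind(
    data.frame(barcode_id = "b1", edit_id = "e1", replicate = "R1",
               condition = "1D", timepoint = 0:1, reads = c(100, 100)),
    data.frame(barcode_id = "b2", edit_id = "e1", replicate = "R1",
               condition = "1D", timepoint = 0:1, reads = c(10, 10)),
    data.frame(barcode_id = "b1", edit_id = "e1", replicate = "R2",
               condition = "1D", timepoint = 0:1, reads = c(10, 10)),
    data.frame(barcode_id = "b2", edit_id = "e1", replicate = "R2",
               condition = "1D", timepoint = 0:1, reads = c(100, 100)),
    data.frame(barcode_id = "n1", edit_id = "neutral_1",
               replicate = rep(c("R1", "R2"), each = 2),
               condition = "1D", timepoint = rep(0:1, 2), reads = 5))
  be <- BarcodeExperiment(rows, neutralEdits = "neutral_1")
  rb <- removedBarcodes(removeOutlierBarcodes(be))
  expect_setequal(paste(rb$replicate, rb$barcode_id),
                  c("R1 b1", "R2 b2"))
  # global mode removes one barcode everywhere
  rbg <- removedBarcodes(removeOutlierBarcodes(be, perStream = FALSE))
  expect_equal(nrow(rbg), 1)
})

test_that("aggregation sums retained barcodes and matches a brute-force group sum", {
  be <- makeCounts(
    list(b1 = c(5, 2, 0), b2 = c(7, 1, 3), n1 = c(4, 4, 4)),
    list(b1 = "e1", b2 = "e1", n1 = "neutral_1"), neutral = "neutral_1")
  agg <- aggregateCounts(be)
  m <- SummarizedExperiment::assay(agg, "counts")
  expect_equal(unname(m["e1", ]), c(12, 3, 3))
  expect_equal(unname(m["neutral_1", ]), c(4, 4, 4))  # anchors aggregate to themselves

  # random table vs independent aggregate() oracle
  set.seed(42)
  tab <- expand.grid(barcode_id = sprintf("b%02d", 1:20),
                     replicate = c("R1", "R2"), timepoint = 0:3,
                     stringsAsFactors = FALSE)
  tab$condition <- "1D"
  tab$edit_id <- paste0("e", (match(tab$barcode_id,
                                    sprintf("b%02d", 1:20)) - 1L) %/% 4L)
  tab$reads <- rpois(nrow(tab), 50)
  tab$edit_id[tab$edit_id == "e4"] <- "neutral_1"
  be2 <- BarcodeExperiment(tab, neutralEdits = "neutral_1")
  agg2 <- aggregateCounts(be2)
  oracle <- aggregate(reads ~ edit_id + replicate + timepoint, tab, sum)
  m2 <- SummarizedExperiment::assay(agg2, "counts")
  cd <- SummarizedExperiment::colData(agg2)
  for (i in seq_len(nrow(oracle))) {
    col <- which(cd$replicate == oracle$replicate[i] &
                 cd$timepoint == oracle$timepoint[i])
    expect_equal(unname(m2[oracle$edit_id[i], col]), oracle$reads[i])
  }
})

test_that("all-zero edits are retained and flagged", {
  be <- makeCounts(list(b1 = c(0, 0, 0), n1 = c(4, 4, 4)),
                   list(b1 = "e1", n1 = "neutral_1"), neutral = "neutral_1")
  expect_warning(agg <- aggregateCounts(be), "zero reads")
  expect_true(SummarizedExperiment::rowData(agg)["e1", "all_zero"])
  expect_equal(unname(SummarizedExperiment::assay(agg)["e1", ]), c(0, 0, 0))
})

test_that("naive frequencies normalize per timepoint with pseudocount stabilization", {
  be <- makeCounts(list(b1 = c(10, 0, 2), b2 = c(30, 0, 2),
                        n1 = c(0, 0, 2)),
                   list(b1 = "e1", b2 = "e2", n1 = "neutral_1"),
                   neutral = "neutral_1")
  agg <- aggregateCounts(be)
  fr <- SummarizedExperiment::assay(naiveFrequencies(agg, 0.5), "freq")
  # hand computation at t = 0: (10.5, 30.5, 0.5) / 41.5
  expect_equal(unname(fr[, 1]), c(10.5, 30.5, 0.5) / 41.5)
  expect_equal(unname(colSums(fr)), rep(1, 3))
  # zero pseudocount with an all-zero timepoint names the sample
  expect_error(naiveFrequencies(agg, 0), "t=1")

  # single edit: frequency one everywhere
  be1 <- makeCounts(list(n1 = c(3, 6, 9)), list(n1 = "neutral_1"),
                    neutral = "neutral_1")
  fr1 <- SummarizedExperiment::assay(naiveFrequencies(aggregateCounts(be1)),
                                     "freq")
  expect_true(all(fr1 == 1))
})

test_that("a barcode mapped to two edits is rejected", {
  rows <- data.frame(barcode_id = "b1", edit_id = c("e1", "e2"),
                     replicate = "R1", condition = "1D",
                     timepoint = 0:1, reads = 1)
  expect_error(BarcodeExperiment(rows, neutralEdits = character()),
               "more than one edit")
})
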