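test_that("peaks map to the nearest TSS with the stated tie rule", {
  ann <- data.frame(gene = c("gA", "gB"), chrom = "chr1", strand = "+",
                    tss = c(1000L, 5000L), stringsAsFactors = FALSE)
  pk <- data.frame(chrom = "chr1", start = 990L, end = 1010L, tf = "T",
                   stringsAsFactors = FALSE)
  expect_identical(assign_peaks_to_genes(pk, ann),
                   data.frame(tf = "T", gene = "gA", stringsAsFactors = FALSE))

  # midpoint exactly between two TSSs -> lexicographically smaller symbol
  ann2 <- data.frame(gene = c("gB", "gA"), chrom = "chr1", strand = "+",
                     tss = c(2000L, 3000L), stringsAsFactors = FALSE)
  pk2 <- data.frame(chrom = "chr1", start = 2500L, end = 2501L, tf = "T",
                    stringsAsFactors = FALSE)
  expect_identical(assign_peaks_to_genes(pk2, ann2)$gene, "gA")

  # out-of-window peaks dropped with a message
  pkfar <- data.frame(chrom = "chr1", start = 100000L, end = 100001L,
                      tf = "T", stringsAsFactors = FALSE)
  expect_message(res <- assign_peaks_to_genes(pkfar, ann, window = 1000),
                 "dropped")
  expect_identical(nrow(res), 0L)

  # unknown chromosome -> warning, peaks dropped
  pkchr <- data.frame(chrom = c("chr1", "chrZ"), start = c(990L, 1L),
                      end = c(1010L, 2L), tf = "T", stringsAsFactors = FALSE)
  expect_warning(res2 <- assign_peaks_to_genes(pkchr, ann), "chrZ")
  expect_identical(res2$gene, "gA")

  expect_error(assign_peaks_to_genes(pk, ann[0, ]), "empty")
})

test_that("peak assignment equals the exhaustive nearest-TSS scan", {
  withr::local_seed(99)
  ann <- data.frame(gene = sprintf("g%02d", sample.int(99, 50)),
                    chrom = sample(paste0("chr", 1:3), 50, TRUE),
                    strand = "+",
                    tss = sample.int(2e5, 50), stringsAsFactors = FALSE)
  ann <- ann[!duplicated(ann$gene), , drop = FALSE]
  start <- sample.int(2e5, 500)
  peaks <- data.frame(chrom = sample(paste0("chr", 1:3), 500, TRUE),
                      start = start, end = start + sample(1:2000, 500, TRUE),
                      tf = sample(c("TFa", "TFb"), 500, TRUE),
                      stringsAsFactors = FALSE)
  got <- suppressMessages(assign_peaks_to_genes(peaks, ann, window = 10000))
  want <- oracle_assign(peaks, ann, window = 10000)
  key <- function(d) sort(paste(d$tf, d$gene))
  expect_identical(key(got), key(want))
})

test_that("adding peaks never removes an assigned (tf, gene) pair", {
  withr::local_seed(17)
  ann <- data.frame(gene = sprintf("g%02d", 1:30), chrom = "chr1",
                    strand = "+", tss = sort(sample.int(5e5, 30)),
                    stringsAsFactors = FALSE)
  start <- sample.int(5e5, 200)
  peaks <- data.frame(chrom = "chr1", start = start,
                      end = start + sample(1:500, 200, TRUE), tf = "T",
                      stringsAsFactors = FALSE)
  base <- suppressMessages(assign_peaks_to_genes(peaks[1:100, ], ann))
  full <- suppressMessages(assign_peaks_to_genes(peaks, ann))
  expect_true(all(paste(base$tf, base$gene) %in% paste(full$tf, full$gene)))
})

test_that("overlap networks have the set-algebra node and edge counts", {
  net <- build_overlap_network(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_length(network_nodes(net), 5L)
  expect_identical(nrow(net$edges), 4L)

  star <- build_overlap_network(list(S = paste0("g", 1:5)))
  expect_length(network_nodes(star), 6L)
  expect_identical(nrow(star$edges), 5L)

  withr::local_seed(3)
  sets <- random_target_sets(3L, 2000L)
  big <- build_overlap_network(sets)
  expect_length(big$targets, length(unique(unlist(sets))))
  expect_identical(nrow(big$edges), sum(lengths(lapply(sets, unique))))

  expect_error(build_overlap_network(list(A = "g1", B = character(0))),
               "empty target set")
})

test_that("a TF bound by another TF is represented as a suffixed target node", {
  net <- build_overlap_network(list(Gata4 = c("Tbx20", "g1"),
                                    Tbx20 = "g1"))
  expect_true("Tbx20@target" %in% net$targets)
  expect_false("Tbx20" %in% net$targets)
  expect_identical(membership_signature(net, "Tbx20@target"), "Gata4")
})

test_that("membership signatures follow the edge list and reject misuse", {
  net <- build_overlap_network(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_identical(membership_signature(net, "g2"), c("A", "B"))
  expect_identical(membership_signature(net, "g1"), "A")
  expect_error(membership_signature(net, "nope"), "unknown")
  expect_error(membership_signature(net, "A"), "TF label")

  # signatures of all genes agree with a per-gene edge scan
  withr::local_seed(21)
  rnet <- build_overlap_network(random_target_sets(4L, 200L))
  for (g in sample(rnet$targets, 25L)) {
    scan <- sort(unique(rnet$edges$tf[rnet$edges$target == g]))
    expect_identical(sort(membership_signature(rnet, g)), scan)
  }
})

test_that("overlap_stats partitions targets and computes shared fractions", {
  net <- build_overlap_network(list(A = c("g1", "g2"), B = c("g2", "g3")))
  vs <- overlap_stats(net)
  expect_identical(vs$counts[["A"]], 1L)
  expect_identical(vs$counts[["B"]], 1L)
  expect_identical(vs$counts[["A+B"]], 1L)
  expect_identical(sum(vs$counts), length(net$targets))
  expect_identical(vs$shared_fraction["A", "B"], 0.5)

  disj <- build_overlap_network(list(A = c("g1", "g2"), B = c("g3", "g4")))
  expect_identical(overlap_stats(disj)$shared_fraction["A", "B"], 0)
  expect_identical(overlap_stats(disj)$shared_fraction["B", "A"], 0)
})

test_that("signature counts partition arbitrary generated networks (k <= 5)", {
  withr::local_seed(8)
  for (rep in 1:10) {
    k <- sample(1:5, 1L)
    sets <- random_target_sets(k, sample(50:400, 1L))
    vs <- overlap_stats(build_overlap_network(sets))
    want <- oracle_venn_counts(sets)
    expect_identical(vs$counts[sort(names(vs$counts))],
                     want[sort(names(want))])
    expect_identical(sum(vs$counts), length(unique(unlist(sets))))
  }
})

test_that("sub-network extraction keeps only induced edges and live targets", {
  net <- build_overlap_network(list(A = c("g1", "g2"), B = c("g2", "g3")))
  sub <- subset_network(net, c("A", "B", "g2"))
  expect_identical(sub$targets, "g2")
  expect_identical(nrow(sub$edges), 2L)
  expect_error(subset_network(net, c("g1", "g2")), "every TF")
})
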