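test_that("edge tuples parse, deduplicate and preserve first-appearance order", {
  f <- withr::local_tempfile(lines = "Gata4\tAldh1a2")
  ed <- read_edge_tuples(f)
  expect_identical(ed, data.frame(tf = "Gata4", target = "Aldh1a2",
                                  stringsAsFactors = FALSE))

  f3 <- withr::local_tempfile(lines = rep("Gata4\tAldh1a2", 3L))
  expect_warning(ed3 <- read_edge_tuples(f3), "duplicate")
  expect_identical(nrow(ed3), 1L)

  # 50 random lines over 2 TFs / 30 genes with 5 planted duplicates
  withr::local_seed(42)
  base <- sprintf("TF%d\tg%02d", sample(1:2, 45, TRUE), sample(1:30, 45, TRUE))
  base <- unique(base)
  while (length(base) < 45)
    base <- unique(c(base, sprintf("TF%d\tg%02d", sample(1:2, 1), sample(1:30, 1))))
  lines <- sample(c(base, base[1:5]))
  f50 <- withr::local_tempfile(lines = lines)
  expect_warning(ed50 <- read_edge_tuples(f50), "duplicate")
  # oracle: unique lines computed independently of the reader
  expect_identical(nrow(ed50), length(unique(lines)))
  expect_identical(paste(ed50$tf, ed50$target, sep = "\t"), unique(lines))
})

test_that("edge tuple reader rejects malformed and empty input, detects commas", {
  f <- withr::local_tempfile(lines = c("A\tg1", "loner"))
  expect_error(read_edge_tuples(f), "line 2")
  fe <- withr::local_tempfile(lines = character(0))
  expect_error(read_edge_tuples(fe), "no edge records")
  fc <- withr::local_tempfile(lines = c("# comment", "A,g1", "B,g2"))
  expect_identical(read_edge_tuples(fc)$target, c("g1", "g2"))
})

test_that("gene/value tables parse exactly and reject ambiguity", {
  f <- withr::local_tempfile(lines = c("g1\t4.5", "g2\t-2"))
  gv <- read_gene_values(f)
  expect_identical(gv$values, c(g1 = 4.5, g2 = -2))

  fbad <- withr::local_tempfile(lines = "g1\tabc")
  expect_error(read_gene_values(fbad), "line 1")

  fdup <- withr::local_tempfile(lines = c("g1\t1", "g1\t2"))
  expect_error(read_gene_values(fdup), "ambiguous")

  # 1000 random rows, exact values per an independent line-by-line oracle
  withr::local_seed(7)
  genes <- sprintf("gene%04d", sample.int(9999, 1000))
  vals <- round(stats::rnorm(1000), 6)
  f1k <- withr::local_tempfile(lines = paste0(genes, "\t", vals))
  gv1k <- read_gene_values(f1k)
  expect_length(gv1k$values, 1000L)
  for (i in c(1L, 500L, 1000L))
    expect_identical(unname(gv1k$values[genes[i]]), vals[i])
  expect_identical(unname(gv1k$values[genes]), vals)
})

test_that("COD peaks convert 1-based inclusive to 0-based half-open", {
  f <- withr::local_tempfile(lines = c("rank\tchromosome\tstart\tend",
                                       "1\tchr1\t1001\t1200"))
  pk <- read_cod_peaks(f, "Gata4")
  expect_identical(pk$start, 1000L)
  expect_identical(pk$end, 1200L)
  expect_identical(pk$tf, "Gata4")
  expect_identical(pk$rank, 1L)  # extra column preserved

  # 1-bp peak: start == end in 1-based is internal length 1
  f1 <- withr::local_tempfile(lines = c("chrom\tstart\tend", "chrX\t500\t500"))
  p1 <- read_cod_peaks(f1, "T")
  expect_identical(p1$end - p1$start, 1L)

  fbad <- withr::local_tempfile(lines = c("chrom\tstart\tend", "chr1\t10\t5"))
  expect_error(read_cod_peaks(fbad, "T"), "row 1")
  fmiss <- withr::local_tempfile(lines = c("foo\tbar", "1\t2"))
  expect_error(read_cod_peaks(fmiss, "T"), "found: foo, bar")
})

test_that("coordinate conversion is a bijection and matches a generic parser", {
  withr::local_seed(11)
  start1 <- sample.int(1e6, 200)
  end1 <- start1 + sample(0:5000, 200, TRUE)
  lines <- c("rank\tchromosome\tstart\tend",
             sprintf("%d\tchr%d\t%d\t%d", seq_len(200),
                     sample(1:3, 200, TRUE), start1, end1))
  f <- withr::local_tempfile(lines = lines)
  pk <- read_cod_peaks(f, "TF")
  expect_identical(nrow(pk), 200L)
  # bijection: back-conversion recovers the original 1-based coordinates
  expect_identical(pk$start + 1L, start1)
  expect_identical(pk$end, end1)
  # midpoints agree with an independent re-parse through read.delim
  ref <- utils::read.delim(f)
  expect_identical(floor((pk$start + pk$end) / 2),
                   floor((ref$start - 1 + ref$end) / 2))
})

test_that("SOFT reading collapses probes per gene and drops blank symbols", {
  txt <- make_soft_text(
    c(p1 = "geneA", p2 = "geneA", p3 = "geneB", p4 = ""),
    list(s1 = c(p1 = 10, p2 = 20, p3 = 5, p4 = 99),
         s2 = c(p1 = 30, p2 = 40, p3 = 7, p4 = 99)))
  f <- withr::local_tempfile(lines = txt)
  b <- read_soft_expression(f)
  expect_setequal(b$genes, c("geneA", "geneB"))  # blank-symbol probe dropped
  expect_identical(b$values["geneA", ], c(s1 = 15, s2 = 35))  # medians
  expect_identical(b$values["geneB", ], c(s1 = 5, s2 = 7))

  bmax <- read_soft_expression(f, collapse = "max")
  expect_identical(unname(bmax$values["geneA", "s1"]), 20)
})

test_that("SOFT collapse equals a brute-force group-by oracle at scale", {
  withr::local_seed(5)
  n_probes <- 100L
  genes <- sprintf("G%02d", 1:40)
  p2g <- stats::setNames(sample(genes, n_probes, TRUE),
                         sprintf("probe%03d", seq_len(n_probes)))
  samples <- sprintf("s%d", 1:6)
  vals <- lapply(samples, function(s)
    stats::setNames(round(stats::runif(n_probes, 1, 1000), 3), names(p2g)))
  names(vals) <- samples
  f <- withr::local_tempfile(lines = make_soft_text(p2g, vals))
  b <- read_soft_expression(f, collapse = "median")
  # gene count conservation
  expect_identical(sort(b$genes), sort(unique(unname(p2g))))
  # brute-force oracle: explicit per-gene loop
  for (g in b$genes) for (s in samples) {
    probes <- names(p2g)[p2g == g]
    expect_equal(unname(b$values[g, s]), stats::median(vals[[s]][probes]))
  }
})

test_that("GraphML write -> read is the identity on nodes, edges, types, attrs", {
  net <- build_overlap_network(list(A = c("g1", "g2"), B = c("g2", "g3")))
  net <- suppressMessages(annotate_nodes(
    net, gene_value_map("logfc", c(g1 = 1 / 3, g2 = -2.5, g3 = pi))))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  back <- read_graphml(f)
  expect_same_network(net, back)
  # full double precision round-trip
  expect_identical(unname(back$attrs$logfc["g3"]), pi)
})

test_that("GraphML reader reports structural errors", {
  f <- withr::local_tempfile(fileext = ".graphml")
  writeLines(c(
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="d0" for="node" attr.name="nodetype" attr.type="string"/>',
    '<graph id="G" edgedefault="directed">',
    '<node id="A"><data key="d0">tf</data></node>',
    '<edge source="A" target="ghost"/>',
    '</graph></graphml>'), f)
  expect_error(read_graphml(f), "undeclared node id 'ghost'")

  f2 <- withr::local_tempfile(fileext = ".graphml")
  writeLines(c(
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<graph id="G"><node id="A"/></graph></graphml>'), f2)
  expect_error(read_graphml(f2), "nodetype")
})

test_that("annotation reader enforces uniqueness and strand values", {
  f <- withr::local_tempfile(lines = c("# gene\tchrom\tstrand\ttss",
                                       "gA\tchr1\t+\t1000",
                                       "gB\tchr1\t-\t2000"))
  ann <- read_gene_annotation(f)
  expect_identical(ann$gene, c("gA", "gB"))
  fdup <- withr::local_tempfile(lines = c("gA\tchr1\t+\t1", "gA\tchr2\t-\t2"))
  expect_error(read_gene_annotation(fdup), "duplicate")
  # writer round-trip
  fo <- withr::local_tempfile()
  write_gene_annotation(ann, fo)
  expect_identical(read_gene_annotation(fo), ann)
})
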