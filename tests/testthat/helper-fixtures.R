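# Shared generators and independent oracles used across test files.

# Random per-TF target sets: each gene gets a random non-empty TF subset.
random_target_sets <- function(k, n_genes, tfs = paste0("TF", seq_len(k))) {
  genes <- sprintf("g%05d", seq_len(n_genes))
  mem <- matrix(stats::runif(n_genes * k) < 0.5, n_genes, k)
  none <- !rowSums(mem)
  mem[cbind(which(none), sample.int(k, sum(none), replace = TRUE))] <- TRUE
  empty_tf <- which(!colSums(mem))
  mem[cbind(sample.int(n_genes, length(empty_tf), replace = TRUE), empty_tf)] <- TRUE
  sets <- lapply(seq_len(k), function(j) genes[mem[, j]])
  names(sets) <- tfs
  sets
}

# Independent Venn oracle: membership matrix + string keys, no tf_network.
oracle_venn_counts <- function(target_sets) {
  genes <- sort(unique(unlist(target_sets, use.names = FALSE)))
  mem <- vapply(target_sets, function(s) genes %in% s, logical(length(genes)))
  if (is.null(dim(mem))) mem <- matrix(mem, nrow = length(genes))
  keys <- apply(mem, 1L, function(r)
    paste(names(target_sets)[r], collapse = "+"))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

# Exhaustive nearest-TSS assignment oracle, O(peaks x genes).
oracle_assign <- function(peaks, annotation, window) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    ann <- annotation[annotation$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(ann)) next
    m <- floor((peaks$start[i] + peaks$end[i]) / 2)
    d <- abs(ann$tss - m)
    if (min(d) > window) next
    out[[length(out) + 1L]] <- data.frame(
      tf = peaks$tf[i], gene = min(ann$gene[d == min(d)]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(tf = character(), gene = character()))
  unique(do.call(rbind, out))
}

# Two-sided unpaired t-test oracle: hand-computed statistic + numerical
# integration of the explicit t density (independent of R's pt()).
oracle_t_pvalue <- function(a, b, var_equal = TRUE) {
  na <- length(a); nb <- length(b)
  if (var_equal) {
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    va <- stats::var(a) / na; vb <- stats::var(b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  }
  tstat <- abs((mean(a) - mean(b)) / se)
  dens <- function(x)
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, tstat, Inf, rel.tol = 1e-13,
                       abs.tol = 1e-14)$value
}

# Small attributed random network for round-trip tests.
random_attributed_network <- function(k = 2L, n_genes = 10L) {
  sets <- random_target_sets(k, n_genes)
  net <- build_overlap_network(sets)
  vals <- stats::setNames(stats::rnorm(length(net$targets)), net$targets)
  suppressMessages(annotate_nodes(net, gene_value_map("logfc", vals)))
}

# Minimal multi-probe SOFT text (several probes per gene) for collapse tests.
make_soft_text <- function(probe2gene, sample_values) {
  lines <- c("^PLATFORM = test_platform",
             "!platform_table_begin", "ID\tGENE_SYMBOL",
             paste0(names(probe2gene), "\t", probe2gene),
             "!platform_table_end")
  for (s in names(sample_values)) {
    v <- sample_values[[s]]
    lines <- c(lines, paste0("^SAMPLE = ", s),
               "!sample_table_begin", "ID_REF\tVALUE",
               paste0(names(v), "\t", v),
               "!sample_table_end")
  }
  lines
}

expect_same_network <- function(a, b) {
  expect_identical(a$tfs, b$tfs)
  expect_setequal(a$targets, b$targets)
  key <- function(e) sort(paste(e$tf, e$target))
  expect_identical(key(a$edges), key(b$edges))
  expect_identical(sort(as.character(names(a$attrs))),
                   sort(as.character(names(b$attrs))))
  for (nm in names(a$attrs)) {
    av <- a$attrs[[nm]]; bv <- b$attrs[[nm]][names(av)]
    expect_identical(unname(av), unname(bv))
  }
}
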