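#' Log2 fold change between two sample groups
#'
#' Per gene, `log2((mean(group_num) + eps) / (mean(group_den) + eps))` on
#' linear-scale intensities. The ratio of arithmetic group means is used (not
#' the mean of per-sample log ratios); an optional pseudocount stabilises
#' genes near zero intensity.
#'
#' @param bundle an [expression_bundle()] with group labels assigned.
#' @param group_num,group_den group labels of the numerator and denominator
#'   condition (e.g. `"heart"`, `"tail"`).
#' @param pseudocount epsilon added to both group means before the ratio
#'   (default 0).
#' @return a [gene_value_map()] named `"logfc"`.
#' @examples
#' b <- expression_bundle("g1", c("s1", "s2"), matrix(c(16, 1), 1),
#'                        groups = c(s1 = "heart", s2 = "tail"))
#' compute_log_fc(b, "heart", "tail")$values  # 4
#' @export
compute_log_fc <- function(bundle, group_num, group_den, pseudocount = 0) {
  if (is.null(bundle$groups)) stop2("bundle has no group labels; see set_groups()")
  if (pseudocount < 0) stop2("pseudocount must be >= 0")
  num <- bundle$samples[bundle$groups == group_num]
  den <- bundle$samples[bundle$groups == group_den]
  if (!length(num)) stop2("no samples in group '", group_num, "'")
  if (!length(den)) stop2("no samples in group '", group_den, "'")
  m_num <- rowMeans(bundle$values[, num, drop = FALSE]) + pseudocount
  m_den <- rowMeans(bundle$values[, den, drop = FALSE]) + pseudocount
  bad <- which(m_num <= 0 | m_den <= 0)
  if (length(bad))
    stop2("non-positive group mean for gene '", bundle$genes[bad[1L]],
          "'; supply a pseudocount > 0")
  gene_value_map("logfc",
                 stats::setNames(log2(m_num / m_den), bundle$genes))
}

#' Per-gene unpaired t-test p-values between two groups
#'
#' Two-sided unpaired t-test per gene; the default is the Student
#' (equal-variance) flavour, with Welch selectable. Degenerate genes where
#' both groups have zero variance get `p = 1` when the means are equal and
#' `p = 0` otherwise (counts reported via a message), so that downstream
#' numeric filters always see an orderable value.
#'
#' @param bundle an [expression_bundle()] with group labels assigned.
#' @param groupA,groupB the two group labels.
#' @param variant `"student"` (default) or `"welch"`.
#' @return a [gene_value_map()] named `"pvalue"`.
#' @export
compute_group_pvalues <- function(bundle, groupA, groupB,
                                  variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (is.null(bundle$groups)) stop2("bundle has no group labels; see set_groups()")
  sa <- bundle$samples[bundle$groups == groupA]
  sb <- bundle$samples[bundle$groups == groupB]
  if (length(sa) < 2L || length(sb) < 2L)
    stop2("each group needs >= 2 samples (got ", length(sa), " and ",
          length(sb), ")")
  xa <- bundle$values[, sa, drop = FALSE]
  xb <- bundle$values[, sb, drop = FALSE]
  p <- numeric(length(bundle$genes))
  n_degen <- 0L
  for (i in seq_along(p)) {
    a <- xa[i, ]
    b <- xb[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      p[i] <- if (mean(a) == mean(b)) 1 else 0
      n_degen <- n_degen + 1L
    } else {
      p[i] <- stats::t.test(a, b, var.equal = variant == "student")$p.value
    }
  }
  if (n_degen > 0L)
    message(sprintf("compute_group_pvalues: %d zero-variance gene(s) assigned p by convention",
                    n_degen))
  gene_value_map("pvalue", stats::setNames(p, bundle$genes))
}

#' Attach a per-gene value map to network nodes
#'
#' Every node (target or TF) whose label appears in the map receives the
#' value under `attrs[[map$name]]`. Target genes absent from the map are
#' handled per `missing`: `"skip"` (default) leaves them unannotated —
#' numeric filters treat them as non-passing — `"zero"` assigns 0, `"error"`
#' aborts listing the first unmatched symbols. A TF absent from the map is
#' always left unannotated.
#'
#' @param net a [tf_network()].
#' @param map a [gene_value_map()].
#' @param missing `"skip"`, `"zero"` or `"error"`.
#' @return the network with the attribute attached.
#' @export
annotate_nodes <- function(net, map, missing = c("skip", "zero", "error")) {
  missing <- match.arg(missing)
  if (!inherits(map, "gene_value_map")) stop2("map must be a gene_value_map")
  if (!length(map$values)) stop2("value map is empty")
  nodes <- network_nodes(net)
  matched <- intersect(nodes, names(map$values))
  # the missing policy governs target genes; a TF absent from the map is
  # simply left unannotated (maps usually cover genes, not hubs)
  unmatched <- setdiff(net$targets, matched)
  if (missing == "error" && length(unmatched))
    stop2(length(unmatched), " target(s) missing from the value map: ",
          paste(utils::head(sort(unmatched), 10L), collapse = ", "))
  vals <- map$values[matched]
  if (missing == "zero" && length(unmatched))
    vals <- c(vals, stats::setNames(rep(0, length(unmatched)), unmatched))
  net$attrs[[map$name]] <- vals
  message(sprintf("annotate_nodes: '%s' set on %d node(s); %d unmatched",
                  map$name, length(matched), length(unmatched)))
  net
}
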