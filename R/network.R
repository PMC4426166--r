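#' Bipartite TF / target-gene network
#'
#' A `tf_network` is a bipartite graph with a small number of high-degree
#' transcription-factor (TF) hub nodes and many low-degree target-gene nodes.
#' TF and target identities are disjoint by construction: a gene that is both
#' a TF of the network and a target of another TF is represented as a separate
#' target node labelled `"<gene>@target"` (see [build_overlap_network()]).
#'
#' @param tfs character vector of TF labels; the order is fixed at
#'   construction and drives the circular layout and canonical signature
#'   ordering.
#' @param targets character vector of target-gene symbols.
#' @param edges data frame with character columns `tf` and `target`; each row
#'   is one regulatory edge. Duplicate rows are collapsed.
#' @param attrs named list of per-node numeric attribute vectors; each element
#'   is a named numeric vector keyed by node label (e.g. `logfc`, `pvalue`).
#'
#' @return object of class `tf_network` with fields `tfs`, `targets`, `edges`,
#'   `attrs`.
#' @seealso [build_overlap_network()], [overlap_stats()]
#' @export
tf_network <- function(tfs, targets, edges, attrs = list()) {
  tfs <- as.character(tfs)
  targets <- as.character(targets)
  edges <- unique(data.frame(tf = as.character(edges$tf),
                             target = as.character(edges$target),
                             stringsAsFactors = FALSE))
  net <- structure(list(tfs = tfs, targets = targets, edges = edges,
                        attrs = attrs),
                   class = "tf_network")
  validate_tf_network(net)
  net
}

validate_tf_network <- function(net) {
  if (!length(net$tfs)) stop2("network must have at least one TF")
  if (anyDuplicated(net$tfs)) stop2("duplicate TF labels")
  if (anyDuplicated(net$targets)) stop2("duplicate target labels")
  overlap <- intersect(net$tfs, net$targets)
  if (length(overlap))
    stop2("labels used as both TF and target: ",
          paste(utils::head(overlap, 5L), collapse = ", "))
  bad_tf <- setdiff(net$edges$tf, net$tfs)
  if (length(bad_tf)) stop2("edge references undeclared TF: ", bad_tf[1L])
  bad_tg <- setdiff(net$edges$target, net$targets)
  if (length(bad_tg)) stop2("edge references undeclared target: ", bad_tg[1L])
  orphan <- setdiff(net$targets, net$edges$target)
  if (length(orphan))
    stop2("target with no incident edge: ", orphan[1L])
  invisible(net)
}

#' @export
print.tf_network <- function(x, ...) {
  cat(sprintf("tf_network: %d TFs (%s), %d targets, %d edges\n",
              length(x$tfs), paste(x$tfs, collapse = ", "),
              length(x$targets), nrow(x$edges)))
  if (length(x$attrs))
    cat("  node attributes:", paste(names(x$attrs), collapse = ", "), "\n")
  invisible(x)
}

#' All node labels of a network
#' @param net a [tf_network()].
#' @return character vector, TFs first then targets.
#' @export
network_nodes <- function(net) c(net$tfs, net$targets)

#' Build an overlapping TF network from per-TF target sets
#'
#' Nodes are the TFs plus the union of all target sets; there is an edge
#' `(tf, g)` exactly when `g` is in that TF's target set. A gene that equals
#' one of the TF labels (a TF bound near another TF's promoter) is renamed
#' `"<gene>@target"` so that hub and target identities stay disjoint.
#'
#' @param target_sets named list mapping TF label to a character vector of
#'   target genes; every set must be non-empty.
#' @param tf_order optional character vector fixing the TF order (defaults to
#'   `names(target_sets)`).
#' @return a [tf_network()].
#' @examples
#' net <- build_overlap_network(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' length(network_nodes(net))  # 5
#' @export
build_overlap_network <- function(target_sets, tf_order = names(target_sets)) {
  if (is.null(names(target_sets)) || any(!nzchar(names(target_sets))))
    stop2("target_sets must be a named list (TF label -> gene vector)")
  if (!setequal(tf_order, names(target_sets)) ||
      length(tf_order) != length(target_sets))
    stop2("tf_order must be a permutation of names(target_sets)")
  target_sets <- target_sets[tf_order]
  empty <- vapply(target_sets, function(s) length(s) == 0L, logical(1))
  if (any(empty))
    stop2("TF with empty target set has no place in the layout: ",
          paste(tf_order[empty], collapse = ", "))
  rename <- function(g) ifelse(g %in% tf_order, paste0(g, "@target"), g)
  sets <- lapply(target_sets, function(s) unique(rename(as.character(s))))
  edges <- do.call(rbind, lapply(tf_order, function(tf)
    data.frame(tf = tf, target = sets[[tf]], stringsAsFactors = FALSE)))
  tf_network(tfs = tf_order,
             targets = unique(unlist(sets, use.names = FALSE)),
             edges = edges)
}

#' Assign ChIP-seq peaks to genes by nearest TSS
#'
#' Each peak is mapped to the gene whose transcription start site (TSS) is
#' nearest to the peak midpoint (`floor((start + end) / 2)` in the 0-based
#' half-open convention). Peaks with no TSS within `window` bp of the midpoint
#' are dropped (count reported via a message); exact distance ties go to the
#' lexicographically smallest gene symbol. The result is deduplicated per
#' `(tf, gene)` pair.
#'
#' @param peaks data frame of peak records with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `tf`, e.g. from [read_cod_peaks()].
#' @param annotation data frame with columns `gene`, `chrom`, `strand`, `tss`
#'   (0-based), e.g. from [read_gene_annotation()]; one row per gene.
#' @param window maximum midpoint-to-TSS distance in bp (default 10000).
#' @return data frame with character columns `tf` and `gene`, one row per
#'   distinct assigned pair.
#' @export
assign_peaks_to_genes <- function(peaks, annotation, window = 10000L) {
  if (is.null(annotation) || nrow(annotation) == 0L)
    stop2("gene annotation is empty")
  if (!is_finite_number(window) || window <= 0) stop2("window must be > 0")
  if (anyDuplicated(annotation$gene))
    stop2("duplicate gene symbols in annotation")
  if (nrow(peaks) == 0L)
    return(data.frame(tf = character(), gene = character(),
                      stringsAsFactors = FALSE))

  missing_chr <- setdiff(unique(peaks$chrom), unique(annotation$chrom))
  if (length(missing_chr)) {
    n_drop <- sum(peaks$chrom %in% missing_chr)
    warning(sprintf(
      "%d peak(s) on chromosome(s) absent from annotation dropped: %s",
      n_drop, paste(missing_chr, collapse = ", ")), call. = FALSE)
    peaks <- peaks[!peaks$chrom %in% missing_chr, , drop = FALSE]
  }
  if (nrow(peaks) == 0L)
    return(data.frame(tf = character(), gene = character(),
                      stringsAsFactors = FALSE))

  mid <- floor((peaks$start + peaks$end) / 2)
  chroms <- unique(peaks$chrom)
  out <- vector("list", length(chroms))
  n_unassigned <- 0L
  for (i in seq_along(chroms)) {
    pk <- which(peaks$chrom == chroms[i])
    ann <- annotation[annotation$chrom == chroms[i], , drop = FALSE]
    # sorted by (position, symbol): the first row per position is already the
    # lexicographic tie-winner among genes sharing a TSS
    ann <- ann[order(ann$tss, ann$gene), , drop = FALSE]
    pos <- ann$tss
    repgene <- ann$gene[match(pos, pos)]
    m <- mid[pk]
    idx <- findInterval(m, pos)             # last TSS <= midpoint
    n <- length(pos)
    left <- pmax(idx, 1L)
    right <- pmin(idx + 1L, n)
    # among duplicated positions findInterval returns the last index <= m, and
    # idx + 1 is the first index > m; repgene resolves within-position ties
    dl <- ifelse(idx >= 1L, m - pos[left], Inf)
    dr <- ifelse(idx < n, pos[right] - m, Inf)
    # left position can still tie duplicates upward when pos[left] == m
    gl <- repgene[left]
    gr <- repgene[right]
    gene <- ifelse(dl < dr, gl, ifelse(dr < dl, gr, pmin(gl, gr)))
    keep <- pmin(dl, dr) <= window
    n_unassigned <- n_unassigned + sum(!keep)
    out[[i]] <- data.frame(tf = peaks$tf[pk[keep]], gene = gene[keep],
                           stringsAsFactors = FALSE)
  }
  if (n_unassigned > 0L)
    message(sprintf("assign_peaks_to_genes: %d peak(s) with no TSS within %d bp dropped",
                    n_unassigned, as.integer(window)))
  unique(do.call(rbind, out))
}

#' Venn membership signature of a target gene
#'
#' The signature of a gene is the exact subset of the network's TFs that have
#' an edge to it, in the network's canonical TF order.
#'
#' @param net a [tf_network()].
#' @param gene a target-gene symbol present in the network.
#' @return character vector of TF labels (non-empty).
#' @export
membership_signature <- function(net, gene) {
  if (length(gene) != 1L) stop2("gene must be a single symbol")
  if (gene %in% net$tfs)
    stop2("'", gene, "' is a TF label, not a target gene")
  if (!gene %in% net$targets) stop2("unknown target gene '", gene, "'")
  members <- unique(net$edges$tf[net$edges$target == gene])
  net$tfs[net$tfs %in% members]
}

## Signature key per target, vectorised (internal workhorse).
target_signatures <- function(net) {
  tf_rank <- stats::setNames(seq_along(net$tfs), net$tfs)
  ed <- net$edges[order(tf_rank[net$edges$tf]), , drop = FALSE]
  keys <- vapply(split(ed$tf, factor(ed$target, levels = net$targets)),
                 signature_key, character(1))
  stats::setNames(keys, net$targets)
}

#' Venn overlap summary of a TF network
#'
#' Partitions the target genes by membership signature and reports the gene
#' count per Venn region plus, for every ordered TF pair `(A, B)`, the shared
#' fraction `|targets(A) ∩ targets(B)| / |targets(A)|`.
#'
#' @param net a [tf_network()].
#' @return object of class `venn_summary`: list with `counts` (named integer
#'   vector keyed by signature, e.g. `"Gata4+Tbx20"`) and `shared_fraction`
#'   (k x k numeric matrix; entry `[A, B]` is the fraction of A's targets also
#'   targeted by B; diagonal 1).
#' @export
overlap_stats <- function(net) {
  sigs <- target_signatures(net)
  counts <- table(sigs)
  counts <- stats::setNames(as.integer(counts), names(counts))
  k <- length(net$tfs)
  shared <- matrix(NA_real_, k, k, dimnames = list(net$tfs, net$tfs))
  tsets <- lapply(net$tfs, function(tf) net$edges$target[net$edges$tf == tf])
  names(tsets) <- net$tfs
  for (a in net$tfs) for (b in net$tfs)
    shared[a, b] <- length(intersect(tsets[[a]], tsets[[b]])) / length(tsets[[a]])
  structure(list(counts = counts, shared_fraction = shared,
                 n_targets = length(net$targets)),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("Venn regions (signature: gene count):\n")
  for (key in names(x$counts))
    cat(sprintf("  %-30s %d\n", key, x$counts[[key]]))
  cat(sprintf("Total target genes: %d\n", x$n_targets))
  k <- nrow(x$shared_fraction)
  if (k > 1L) {
    cat("Shared targets (% of row TF's targets also bound by column TF):\n")
    for (a in rownames(x$shared_fraction)) for (b in colnames(x$shared_fraction))
      if (a != b)
        cat(sprintf("  %s & %s: %.0f%%\n", a, b, 100 * x$shared_fraction[a, b]))
  }
  invisible(x)
}

#' Serialise a Venn summary to a list suitable for JSON output
#' @param x a `venn_summary`.
#' @return plain list with counts, shared fractions and target total.
#' @export
venn_summary_list <- function(x) {
  sf <- list()
  for (a in rownames(x$shared_fraction)) for (b in colnames(x$shared_fraction))
    if (a != b) sf[[paste0(a, "->", b)]] <- unname(x$shared_fraction[a, b])
  list(counts = as.list(x$counts), shared_fraction = sf,
       n_targets = x$n_targets)
}
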