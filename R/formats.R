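#' Read TF network edge tuples
#'
#' Reads a two-column `<tf, target>` tuple file (tab- or comma-separated;
#' `auto` prefers tab and falls back to comma). Empty lines and lines starting
#' with `#` are skipped. Duplicate pairs collapse to one with a warning; first
#' appearance order is preserved.
#'
#' @param path file path.
#' @param delimiter one of `"auto"`, `"tab"`, `"comma"`.
#' @return data frame with character columns `tf`, `target`.
#' @export
read_edge_tuples <- function(path, delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!any(keep)) stop2("no edge records in ", path)
  sep <- resolve_delimiter(delimiter, lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop2("malformed edge line ", lineno[which(nf < 2L)[1L]],
          ": fewer than 2 fields")
  tf <- trimws(vapply(parts, `[[`, character(1), 1L))
  target <- trimws(vapply(parts, `[[`, character(1), 2L))
  dup <- duplicated(paste0(tf, "\r", target))
  if (any(dup))
    warning(sprintf("%d duplicate edge line(s) collapsed", sum(dup)),
            call. = FALSE)
  data.frame(tf = tf[!dup], target = target[!dup], stringsAsFactors = FALSE)
}

#' Write TF network edge tuples
#' @param edges data frame with columns `tf`, `target`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_edge_tuples <- function(edges, path, sep = "\t") {
  writeLines(paste(edges$tf, edges$target, sep = sep), path)
  invisible(path)
}

#' Per-gene numeric value map
#'
#' Container for one named per-gene statistic (log2 fold change, p-value, or
#' any user-supplied numeric property).
#'
#' @param name attribute label, e.g. `"logfc"` or `"pvalue"`.
#' @param values named numeric vector, gene symbol -> finite value.
#' @return object of class `gene_value_map` with fields `name`, `values`.
#' @export
gene_value_map <- function(name, values) {
  if (!nzchar(name)) stop2("attribute name must be non-empty")
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop2("values must be a named numeric vector")
  if (anyDuplicated(names(values)))
    stop2("duplicate gene symbols in value map")
  if (any(!is.finite(values)))
    stop2("non-finite values for: ",
          paste(utils::head(names(values)[!is.finite(values)], 5L),
                collapse = ", "))
  if (identical(name, "pvalue") && (any(values < 0) || any(values > 1)))
    stop2("p-values must lie in [0, 1]")
  structure(list(name = name, values = values), class = "gene_value_map")
}

#' @export
print.gene_value_map <- function(x, ...) {
  cat(sprintf("gene_value_map '%s': %d genes, range [%g, %g]\n",
              x$name, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Read a two-column gene/value table
#'
#' Parses `<gene, value>` tuples (tab- or comma-separated). Duplicate gene
#' symbols are an error (the value would be ambiguous), as is any second
#' field that does not parse as a number.
#'
#' @inheritParams read_edge_tuples
#' @param name attribute label for the resulting map (default `"value"`).
#' @return a [gene_value_map()].
#' @export
read_gene_values <- function(path, name = "value",
                             delimiter = c("auto", "tab", "comma")) {
  delimiter <- match.arg(delimiter)
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!any(keep)) stop2("no records in ", path)
  sep <- resolve_delimiter(delimiter, lines)
  lineno <- which(keep)
  parts <- strsplit(lines[keep], sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop2("malformed line ", lineno[which(nf < 2L)[1L]],
          ": fewer than 2 fields")
  gene <- trimws(vapply(parts, `[[`, character(1), 1L))
  raw <- trimws(vapply(parts, `[[`, character(1), 2L))
  val <- suppressWarnings(as.numeric(raw))
  if (anyNA(val))
    stop2("non-numeric value '", raw[which(is.na(val))[1L]], "' at line ",
          lineno[which(is.na(val))[1L]])
  if (anyDuplicated(gene))
    stop2("duplicate gene '", gene[duplicated(gene)][1L],
          "': value would be ambiguous")
  gene_value_map(name, stats::setNames(val, gene))
}

#' Write a gene/value map as a two-column table
#' @param map a [gene_value_map()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_gene_values <- function(map, path, sep = "\t") {
  writeLines(paste(names(map$values),
                   sprintf("%.17g", unname(map$values)), sep = sep), path)
  invisible(path)
}

#' Read a COD-style ChIP-seq peak list
#'
#' Tab-delimited with a header row; the chromosome, start and end columns are
#' located by case-insensitive name match (`chromosome`/`chrom`, `start`,
#' `end`) so CisGenome-style dialect variants parse without configuration.
#' Input coordinates are 1-based inclusive and are converted to the package's
#' internal 0-based half-open convention (`start - 1`, `end`); a row with
#' `start == end` is a valid 1-bp peak. All other columns are preserved.
#'
#' @param path file path.
#' @param tf_label TF label attached to every peak.
#' @return data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `tf`, plus any extra columns from the file.
#' @export
read_cod_peaks <- function(path, tf_label) {
  if (!file.exists(path)) stop2("file not found: ", path)
  if (missing(tf_label) || !nzchar(tf_label)) stop2("tf_label is required")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  hdr <- tolower(names(tab))
  find_col <- function(alts) {
    hit <- which(hdr %in% alts)
    if (!length(hit))
      stop2("COD header lacks a ", alts[1L], " column; found: ",
            paste(names(tab), collapse = ", "))
    hit[1L]
  }
  ci <- find_col(c("chromosome", "chrom", "chr"))
  si <- find_col("start")
  ei <- find_col("end")
  start1 <- as.integer(tab[[si]])
  end1 <- as.integer(tab[[ei]])
  if (anyNA(start1) || anyNA(end1))
    stop2("non-integer coordinate at data row ",
          which(is.na(start1) | is.na(end1))[1L])
  start0 <- start1 - 1L
  end0 <- end1
  bad <- which(end0 <= start0)
  if (length(bad))
    stop2("peak with end < start at data row ", bad[1L])
  extra <- tab[, -c(ci, si, ei), drop = FALSE]
  out <- data.frame(chrom = as.character(tab[[ci]]), start = start0,
                    end = end0, tf = tf_label, stringsAsFactors = FALSE)
  if (ncol(extra)) out <- cbind(out, extra)
  if (any(!nzchar(out$chrom))) stop2("empty chromosome name in ", path)
  out
}

#' Read a gene annotation table
#'
#' Four tab-separated columns: gene symbol, chromosome, strand (`+`/`-`) and
#' TSS position (0-based). Lines starting with `#` are comments; a header row
#' whose first field is `gene` is skipped. Duplicate gene symbols are
#' rejected.
#'
#' @param path file path.
#' @return data frame with columns `gene`, `chrom`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 4L) stop2("annotation needs 4 columns (gene, chrom, strand, tss)")
  if (identical(tolower(tab[1, 1]), "gene")) tab <- tab[-1L, , drop = FALSE]
  out <- data.frame(gene = as.character(tab[[1L]]),
                    chrom = as.character(tab[[2L]]),
                    strand = as.character(tab[[3L]]),
                    tss = as.integer(tab[[4L]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene))
    stop2("duplicate gene in annotation: ", out$gene[duplicated(out$gene)][1L])
  if (any(!out$strand %in% c("+", "-")))
    stop2("strand must be + or -")
  if (anyNA(out$tss) || any(out$tss < 0L)) stop2("tss must be integer >= 0")
  out
}

#' Write a gene annotation table
#' @param annotation data frame with columns `gene`, `chrom`, `strand`, `tss`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene\tchrom\tstrand\ttss (0-based)", con)
  writeLines(paste(annotation$gene, annotation$chrom, annotation$strand,
                   annotation$tss, sep = "\t"), con)
  invisible(path)
}

#' Expression bundle
#'
#' Gene x sample matrix of linear-scale intensities with per-sample group
#' labels.
#'
#' @param genes ordered gene symbols (unique).
#' @param samples ordered sample names.
#' @param values numeric matrix, `length(genes)` x `length(samples)`,
#'   positive reals.
#' @param groups optional named character vector mapping sample -> group
#'   label; may be `NULL` until assigned (e.g. via [set_groups()]).
#' @return object of class `expression_bundle`.
#' @export
expression_bundle <- function(genes, samples, values, groups = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != length(genes) || ncol(values) != length(samples))
    stop2("matrix dimensions do not match gene/sample lists")
  if (anyDuplicated(genes)) stop2("gene symbols must be unique")
  if (!is.null(groups)) {
    if (!all(samples %in% names(groups)))
      stop2("every sample needs a group label")
    groups <- groups[samples]
  }
  dimnames(values) <- list(genes, samples)
  structure(list(genes = genes, samples = samples, values = values,
                 groups = groups),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("expression_bundle: %d genes x %d samples\n",
              length(x$genes), length(x$samples)))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%s=%s", names(x$groups), x$groups),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Assign sample group labels to an expression bundle
#' @param bundle an [expression_bundle()].
#' @param groups named character vector, sample -> group label, covering every
#'   sample.
#' @return the bundle with groups set.
#' @export
set_groups <- function(bundle, groups) {
  expression_bundle(bundle$genes, bundle$samples, bundle$values, groups)
}

#' Read a GEO SOFT expression file
#'
#' Parses the platform table (probe -> gene symbol) and every sample table
#' (probe -> VALUE) of a SOFT file, then collapses probes mapping to the same
#' gene symbol with the chosen rule (default median). Probes with an empty
#' gene symbol are dropped. Sample group labels are left unset; assign them
#' afterwards with [set_groups()].
#'
#' @param path file path.
#' @param gene_column name of the platform-table column holding gene symbols
#'   (default `"GENE_SYMBOL"`).
#' @param collapse probe-collapse rule: `"median"`, `"mean"` or `"max"`.
#' @return an [expression_bundle()] with `groups = NULL`.
#' @export
read_soft_expression <- function(path, gene_column = "GENE_SYMBOL",
                                 collapse = c("median", "mean", "max")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  read_block <- function(begin_tag, end_tag, from) {
    b <- which(lines == begin_tag)
    b <- b[b > from][1L]
    if (is.na(b)) return(NULL)
    e <- which(lines == end_tag)
    e <- e[e > b][1L]
    if (is.na(e)) stop2("unterminated table block after line ", b)
    tab <- utils::read.delim(text = lines[(b + 1L):(e - 1L)], header = TRUE,
                             sep = "\t", check.names = FALSE,
                             stringsAsFactors = FALSE,
                             colClasses = "character")
    list(table = tab, end = e)
  }

  plat_start <- grep("^\\^PLATFORM", lines)
  if (!length(plat_start)) stop2("no ^PLATFORM section in ", path)
  plat <- read_block("!platform_table_begin", "!platform_table_end",
                     plat_start[1L])
  if (is.null(plat)) stop2("no platform table in ", path)
  ptab <- plat$table
  if (!"ID" %in% names(ptab)) stop2("platform table lacks an ID column")
  if (!gene_column %in% names(ptab))
    stop2("platform table lacks column '", gene_column, "'; found: ",
          paste(names(ptab), collapse = ", "))
  probe2gene <- stats::setNames(trimws(ptab[[gene_column]]),
                                trimws(ptab$ID))

  sample_starts <- grep("^\\^SAMPLE", lines)
  if (!length(sample_starts)) stop2("no ^SAMPLE sections in ", path)
  sample_names <- sub("^\\^SAMPLE\\s*=\\s*", "", lines[sample_starts])
  cols <- vector("list", length(sample_starts))
  for (i in seq_along(sample_starts)) {
    blk <- read_block("!sample_table_begin", "!sample_table_end",
                      sample_starts[i])
    if (is.null(blk)) stop2("sample '", sample_names[i], "' has no table")
    stab <- blk$table
    if (!all(c("ID_REF", "VALUE") %in% names(stab)))
      stop2("sample '", sample_names[i], "' table lacks ID_REF/VALUE columns")
    v <- suppressWarnings(as.numeric(stab$VALUE))
    if (anyNA(v)) stop2("non-numeric VALUE in sample '", sample_names[i], "'")
    cols[[i]] <- stats::setNames(v, trimws(stab$ID_REF))
  }

  probes <- names(probe2gene)[nzchar(probe2gene)]
  genes <- unique(probe2gene[probes])
  fun <- switch(collapse, median = stats::median, mean = mean, max = max)
  mat <- matrix(NA_real_, length(genes), length(sample_names),
                dimnames = list(genes, sample_names))
  for (j in seq_along(cols)) {
    agg <- tapply(cols[[j]][probes], probe2gene[probes], fun)
    mat[names(agg), j] <- agg
  }
  if (anyNA(mat)) stop2("probe present in platform table missing from a sample table")
  expression_bundle(genes, sample_names, mat)
}

## ---- GraphML ---------------------------------------------------------------

graphml_ns <- "http://graphml.graphdrawing.org/xmlns"

#' Write a TF network as GraphML
#'
#' Emits one string node attribute carrying the node type (TF vs target) and
#' one double attribute per numeric node attribute, serialised with full
#' round-trip precision; an optional layout adds `x`/`y` double attributes.
#'
#' @param net a [tf_network()].
#' @param path output file path.
#' @param nodetype_attr name of the node-type attribute (default
#'   `"nodetype"`, values `"tf"`/`"target"`).
#' @param layout optional `tf_layout` from [place_nodes()]; its coordinates
#'   are embedded as `x` and `y` node attributes.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, nodetype_attr = "nodetype",
                          layout = NULL) {
  attrs <- net$attrs
  if (!is.null(layout)) {
    pos <- layout$positions
    attrs$x <- stats::setNames(pos$x, pos$node)
    attrs$y <- stats::setNames(pos$y, pos$node)
  }
  doc <- xml2::xml_new_root("graphml", xmlns = graphml_ns)
  key0 <- xml2::xml_add_child(doc, "key", id = "d0", "for" = "node",
                              attr.name = nodetype_attr, attr.type = "string")
  keys <- character(length(attrs))
  for (i in seq_along(attrs)) {
    keys[i] <- paste0("d", i)
    xml2::xml_add_child(doc, "key", id = keys[i], "for" = "node",
                        attr.name = names(attrs)[i], attr.type = "double")
  }
  graph <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "directed")
  add_node <- function(id, type) {
    nd <- xml2::xml_add_child(graph, "node", id = id)
    d <- xml2::xml_add_child(nd, "data", key = "d0")
    xml2::xml_text(d) <- type
    for (i in seq_along(attrs)) {
      v <- attrs[[i]][id]
      if (!is.na(v)) {
        dd <- xml2::xml_add_child(nd, "data", key = keys[i])
        xml2::xml_text(dd) <- sprintf("%.17g", unname(v))
      }
    }
  }
  for (tf in net$tfs) add_node(tf, "tf")
  for (tg in net$targets) add_node(tg, "target")
  for (r in seq_len(nrow(net$edges)))
    xml2::xml_add_child(graph, "edge",
                        source = net$edges$tf[r],
                        target = net$edges$target[r])
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a TF network from GraphML
#'
#' Nodes must carry a string attribute distinguishing TFs from targets
#' (default name `"nodetype"`, values `"tf"`/`"target"`); numeric (`double`,
#' `float`, `int`, `long`) node attributes become network attributes. Edges
#' must run TF -> target.
#'
#' @param path GraphML file path.
#' @param nodetype_attr name of the node-type attribute.
#' @return a [tf_network()]; if the file embeds `x`/`y` attributes they are
#'   returned in `attrs` like any other numeric attribute.
#' @export
read_graphml <- function(path, nodetype_attr = "nodetype") {
  if (!file.exists(path)) stop2("file not found: ", path)
  doc <- xml2::read_xml(path)
  ns <- c(g = graphml_ns)
  key_nodes <- xml2::xml_find_all(doc, ".//g:key[@for='node']", ns)
  key_id <- xml2::xml_attr(key_nodes, "id")
  key_name <- xml2::xml_attr(key_nodes, "attr.name")
  key_type <- xml2::xml_attr(key_nodes, "attr.type")
  type_key <- key_id[key_name == nodetype_attr]
  if (!length(type_key))
    stop2("GraphML lacks a node attribute '", nodetype_attr,
          "'; declare a <key for=\"node\" attr.name=\"", nodetype_attr,
          "\" attr.type=\"string\"> (or pass nodetype_attr=) with values ",
          "'tf'/'target'")
  num_keys <- key_id[key_type %in% c("double", "float", "int", "long") &
                       key_name != nodetype_attr]
  num_names <- key_name[match(num_keys, key_id)]

  nodes <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  ids <- xml2::xml_attr(nodes, "id")
  types <- character(length(ids))
  attrs <- stats::setNames(
    replicate(length(num_keys), numeric(0), simplify = FALSE), num_names)
  for (i in seq_along(nodes)) {
    data <- xml2::xml_find_all(nodes[[i]], "./g:data", ns)
    dkeys <- xml2::xml_attr(data, "key")
    dvals <- xml2::xml_text(data)
    ti <- match(type_key[1L], dkeys)
    if (is.na(ti))
      stop2("node '", ids[i], "' has no '", nodetype_attr, "' value")
    types[i] <- dvals[ti]
    for (j in seq_along(num_keys)) {
      kj <- match(num_keys[j], dkeys)
      if (!is.na(kj))
        attrs[[j]][ids[i]] <- as.numeric(dvals[kj])
    }
  }
  if (any(!types %in% c("tf", "target")))
    stop2("node type values must be 'tf' or 'target'")
  edges <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  src <- xml2::xml_attr(edges, "source")
  dst <- xml2::xml_attr(edges, "target")
  unknown <- setdiff(c(src, dst), ids)
  if (length(unknown))
    stop2("edge references undeclared node id '", unknown[1L], "'")
  attrs <- attrs[vapply(attrs, length, integer(1)) > 0L]
  tf_network(tfs = ids[types == "tf"], targets = ids[types == "target"],
             edges = data.frame(tf = src, target = dst,
                                stringsAsFactors = FALSE),
             attrs = attrs)
}
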