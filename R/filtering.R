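#' Parse a numeric node-filter expression
#'
#' Grammar: `clause := [abs(] IDENT [)] CMP NUMBER` with
#' `CMP` one of `<`, `<=`, `>`, `>=`; clauses combine with a single kind of
#' `and`/`or` (no parentheses, no mixing). Whitespace-insensitive; numbers
#' accept scientific notation.
#'
#' Typical expressions: `"logfc > 4 or logfc < -4"` (the complement of
#' "between -4 and 4"), `"abs(logfc) > 4"`, `"pvalue < 0.001"`.
#'
#' @param text expression string.
#' @return object of class `filter_predicate`: list with `clauses` (each a
#'   list `attr`, `cmp`, `threshold`, `abs`) and `combinator`
#'   (`"and"`/`"or"`).
#' @export
parse_filter <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop2("filter expression must be a non-empty string")
  has_and <- grepl("\\band\\b", text, ignore.case = TRUE)
  has_or <- grepl("\\bor\\b", text, ignore.case = TRUE)
  if (has_and && has_or)
    stop2("mixed 'and'/'or' in one expression is not supported ",
          "(parenthesised nesting is out of scope)")
  combinator <- if (has_or) "or" else "and"
  parts <- strsplit(text, "\\s+(?i:and|or)\\s+", perl = TRUE)[[1L]]
  clause_re <- paste0(
    "^\\s*(abs\\s*\\(\\s*)?",              # optional abs(
    "([A-Za-z_][A-Za-z0-9_.]*)",           # attribute identifier
    "(\\s*\\))?\\s*",                      # closing paren
    "(<=|>=|==|!=|<|>|=)\\s*",             # comparator (invalid ones caught)
    "([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*$")
  clauses <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    m <- regmatches(parts[i], regexec(clause_re, parts[i]))[[1L]]
    if (!length(m)) {
      cmp_pos <- regexpr("<=|>=|<|>|=|!", parts[i])
      stop2("cannot parse clause '", trimws(parts[i]), "'",
            if (cmp_pos < 0) " (missing comparator)" else "")
    }
    has_abs <- nzchar(m[2L])
    if (has_abs != nzchar(m[4L]))
      stop2("unbalanced abs() in clause '", trimws(parts[i]), "'")
    cmp <- m[5L]
    if (!cmp %in% c("<", "<=", ">", ">="))
      stop2("unsupported comparator '", cmp, "' in clause '",
            trimws(parts[i]), "' at position ",
            regexpr(cmp, parts[i], fixed = TRUE))
    clauses[[i]] <- list(attr = m[3L], cmp = cmp,
                         threshold = as.numeric(m[6L]), abs = has_abs)
  }
  structure(list(clauses = clauses, combinator = combinator),
            class = "filter_predicate")
}

#' @export
print.filter_predicate <- function(x, ...) {
  txt <- vapply(x$clauses, function(cl)
    sprintf("%s%s%s %s %g", if (cl$abs) "abs(" else "", cl$attr,
            if (cl$abs) ")" else "", cl$cmp, cl$threshold), character(1))
  cat("filter_predicate:", paste(txt, collapse = paste0(" ", x$combinator, " ")),
      "\n")
  invisible(x)
}

eval_clause <- function(cl, values) {
  v <- if (cl$abs) abs(values) else values
  out <- switch(cl$cmp,
                "<"  = v < cl$threshold,
                "<=" = v <= cl$threshold,
                ">"  = v > cl$threshold,
                ">=" = v >= cl$threshold)
  out & !is.na(values)
}

#' Classify target genes as up / down / neutral by attribute thresholds
#'
#' Targets with `value > upper` are `up`, `value < lower` are `down`, and
#' everything else — including values exactly at a bound and unannotated
#' nodes — is `neutral` (the inequalities are strict). TF nodes are class
#' `tf`.
#'
#' @param net a [tf_network()].
#' @param attr node attribute name (e.g. `"logfc"`).
#' @param lower,upper class bounds (defaults -4 and 4, i.e. 16-fold change).
#' @return named character vector over all nodes with values in
#'   `c("up", "down", "neutral", "tf")`.
#' @export
classify_by_threshold <- function(net, attr, lower = -4, upper = 4) {
  if (!(lower < upper)) stop2("lower must be < upper")
  vals <- net$attrs[[attr]]
  if (is.null(vals) || !length(vals))
    stop2("attribute '", attr, "' is absent from all nodes")
  v <- vals[net$targets]
  cls <- rep("neutral", length(net$targets))
  cls[!is.na(v) & v > upper] <- "up"
  cls[!is.na(v) & v < lower] <- "down"
  stats::setNames(c(rep("tf", length(net$tfs)), cls), network_nodes(net))
}

#' Apply a filter predicate to a network
#'
#' Target genes satisfying the predicate become `visible`; the rest are
#' `blurred` (mode `"blur"`) or `hidden` (mode `"omit"`). Unannotated targets
#' never satisfy a clause. TFs are always `visible`.
#'
#' @param net a [tf_network()].
#' @param predicate a [parse_filter()] result (a string is parsed for
#'   convenience).
#' @param mode `"blur"` or `"omit"`.
#' @param classes optional up/down/neutral classification from
#'   [classify_by_threshold()]; stored alongside the states for styling. When
#'   omitted all targets are classed `neutral`.
#' @return object of class `visual_state`: list with `state` (named vector
#'   over all nodes, `visible`/`blurred`/`hidden`), `class` (named vector,
#'   `up`/`down`/`neutral`/`tf`) and `counts`.
#' @export
apply_filter <- function(net, predicate, mode = c("blur", "omit"),
                         classes = NULL) {
  mode <- match.arg(mode)
  if (is.character(predicate)) predicate <- parse_filter(predicate)
  if (!inherits(predicate, "filter_predicate"))
    stop2("predicate must be a filter_predicate or expression string")
  attrs_used <- unique(vapply(predicate$clauses, `[[`, character(1), "attr"))
  missing_attr <- setdiff(attrs_used, names(net$attrs))
  if (length(missing_attr))
    stop2("predicate attribute '", missing_attr[1L],
          "' is present on no node")

  vals <- lapply(attrs_used, function(a) net$attrs[[a]][net$targets])
  names(vals) <- attrs_used
  hits <- lapply(predicate$clauses, function(cl) eval_clause(cl, vals[[cl$attr]]))
  pass <- Reduce(if (predicate$combinator == "and") `&` else `|`, hits)
  pass[is.na(pass)] <- FALSE

  st <- ifelse(pass, "visible", if (mode == "blur") "blurred" else "hidden")
  state <- stats::setNames(c(rep("visible", length(net$tfs)), st),
                           network_nodes(net))
  if (is.null(classes))
    classes <- stats::setNames(
      c(rep("tf", length(net$tfs)), rep("neutral", length(net$targets))),
      network_nodes(net))
  if (!setequal(names(classes), network_nodes(net)))
    stop2("classes must cover exactly the network's nodes")
  counts <- c(visible = sum(state == "visible"),
              blurred = sum(state == "blurred"),
              hidden = sum(state == "hidden"))
  n_unann <- sum(Reduce(`|`, lapply(vals, is.na)))
  if (n_unann > 0L)
    message(sprintf("apply_filter: %d unannotated target(s) treated as non-passing",
                    n_unann))
  message(sprintf("apply_filter: %d visible, %d blurred, %d hidden",
                  counts[["visible"]], counts[["blurred"]], counts[["hidden"]]))
  structure(list(state = state, class = classes[names(state)],
                 counts = counts, mode = mode),
            class = "visual_state")
}

#' @export
print.visual_state <- function(x, ...) {
  cat(sprintf("visual_state (%s mode): %d visible, %d blurred, %d hidden\n",
              x$mode, x$counts[["visible"]], x$counts[["blurred"]],
              x$counts[["hidden"]]))
  invisible(x)
}
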