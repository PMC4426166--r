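#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Signature key for a set of TF members
#'
#' Canonical string form of a Venn membership signature: member TF labels
#' joined with "+" in the network's TF order.
#'
#' @param members character vector of TF labels (already in canonical order).
#' @return single string.
#' @keywords internal
signature_key <- function(members) paste(members, collapse = "+")

split_signature_key <- function(key) strsplit(key, "+", fixed = TRUE)[[1L]]

is_finite_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Auto-detect tab vs comma on the first non-empty, non-comment line.
## Tab wins when both are present.
detect_delimiter <- function(lines) {
  for (ln in lines) {
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    if (grepl("\t", ln, fixed = TRUE)) return("\t")
    if (grepl(",", ln, fixed = TRUE)) return(",")
    return("\t")
  }
  "\t"
}

resolve_delimiter <- function(delimiter, lines) {
  switch(delimiter,
    auto  = detect_delimiter(lines),
    tab   = "\t",
    comma = ",",
    stop2("unknown delimiter '", delimiter, "' (use auto, tab or comma)")
  )
}
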