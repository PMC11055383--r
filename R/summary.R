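#' Merge assignment tables from several methods
#'
#' One row per barcode in the union of the tables, one column per method;
#' entries are the singlet label or `doublet`/`negative`, with `NA` where
#' a method did not see the barcode.
#'
#' @param tables List of `assignment_table`s with distinct method names.
#' @return data.frame with a `Barcode` column and one column per method.
#' @export
merge_summaries <- function(tables) {
  if (inherits(tables, "assignment_table")) tables <- list(tables)
  if (!length(tables)) stop("need at least one table")
  methods <- vapply(tables, function(t) t$method_name, character(1))
  if (anyDuplicated(methods)) {
    stop("duplicate method name(s): ",
         paste(unique(methods[duplicated(methods)]), collapse = ", "))
  }
  barcodes <- sort(unique(unlist(lapply(tables, function(t) t$calls$barcode))))
  out <- data.frame(Barcode = barcodes, stringsAsFactors = FALSE)
  for (t in tables) {
    a <- ifelse(t$calls$kind == "singlet", t$calls$label, t$calls$kind)
    out[[t$method_name]] <- a[match(barcodes, t$calls$barcode)]
  }
  out
}

#' Per-method classification tallies
#'
#' @param tables List of `assignment_table`s.
#' @return data.frame `Method`, `Singlet`, `Doublet`, `Negative`, `Total`.
#' @export
classification_counts <- function(tables) {
  if (inherits(tables, "assignment_table")) tables <- list(tables)
  rows <- lapply(tables, function(t) {
    tab <- table(factor(t$calls$kind, c("singlet", "doublet", "negative")))
    data.frame(Method = t$method_name,
               Singlet = as.integer(tab[["singlet"]]),
               Doublet = as.integer(tab[["doublet"]]),
               Negative = as.integer(tab[["negative"]]),
               Total = nrow(t$calls),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
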