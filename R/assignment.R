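#' Per-method cell assignment tables
#'
#' An `assignment_table` holds one demultiplexer's verdict per cell barcode:
#' a singlet label (donor or hashtag), `doublet`, or `negative`.  It is the
#' common currency between hashing and genetic demultiplexing outputs.
#'
#' @param barcodes Character vector of cell barcodes (must be unique).
#' @param assignments Character vector, same length: a singlet label, or a
#'   doublet/negative synonym (matched case-insensitively).
#' @param method_name Name of the demultiplexing method that produced the
#'   table.
#' @param family Either `"hashing"` or `"genetic"`.
#' @param doublet_synonyms,negative_synonyms Strings (case-insensitive)
#'   mapped to the doublet / negative classes; anything else is taken
#'   verbatim as a singlet label.
#'
#' @return An object of class `assignment_table`: a list with elements
#'   `method_name`, `family` and `calls`, the latter a data.frame with
#'   columns `barcode`, `kind` (`singlet`/`doublet`/`negative`) and `label`
#'   (`NA` unless singlet).
#' @export
assignment_table <- function(barcodes, assignments, method_name, family,
                             doublet_synonyms = c("doublet"),
                             negative_synonyms = c("negative", "unassigned")) {
  family <- match.arg(family, c("hashing", "genetic"))
  barcodes <- as.character(barcodes)
  assignments <- as.character(assignments)
  if (length(barcodes) != length(assignments)) {
    stop("'barcodes' and 'assignments' must have the same length")
  }
  dup <- barcodes[duplicated(barcodes)]
  if (length(dup)) {
    stop("duplicate barcode(s) in assignment table: ",
         paste(utils::head(unique(dup), 5L), collapse = ", "))
  }
  low <- tolower(assignments)
  kind <- ifelse(low %in% tolower(doublet_synonyms), "doublet",
          ifelse(low %in% tolower(negative_synonyms), "negative", "singlet"))
  label <- ifelse(kind == "singlet", assignments, NA_character_)
  if (any(kind == "singlet" & (is.na(label) | !nzchar(label)))) {
    stop("singlet assignments must be non-empty strings")
  }
  structure(
    list(method_name = as.character(method_name)[1L],
         family = family,
         calls = data.frame(barcode = barcodes, kind = kind, label = label,
                            stringsAsFactors = FALSE)),
    class = "assignment_table")
}

#' @export
print.assignment_table <- function(x, ...) {
  tab <- table(factor(x$calls$kind, c("singlet", "doublet", "negative")))
  cat(sprintf("assignment_table '%s' (%s): %d barcodes | %d singlet, %d doublet, %d negative | %d labels\n",
              x$method_name, x$family, nrow(x$calls),
              tab[["singlet"]], tab[["doublet"]], tab[["negative"]],
              length(singlet_names(x))))
  invisible(x)
}

#' Distinct singlet labels of an assignment table
#'
#' @param table An `assignment_table`.
#' @return Sorted character vector of distinct singlet labels.
#' @export
singlet_names <- function(table) {
  stopifnot(inherits(table, "assignment_table"))
  sort(unique(table$calls$label[table$calls$kind == "singlet"]))
}

#' Read an assignment table from CSV
#'
#' Expects a header with columns `Barcode` and `Assignment` (an optional
#' `Method` column is ignored).  The strings `doublet` and `negative`
#' (case-insensitive, plus configurable synonyms) map to those classes;
#' every other value is a singlet label.
#'
#' @param path CSV file path.
#' @inheritParams assignment_table
#' @param ... Passed on to [assignment_table()] (synonym lists).
#' @return An `assignment_table`.
#' @export
read_assignment_table <- function(path, method_name, family, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("Barcode", "Assignment")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s) ", paste(miss, collapse = ", "),
         " in ", path, " (expected header 'Barcode,Assignment')")
  }
  assignment_table(df$Barcode, df$Assignment, method_name, family, ...)
}

#' Write an assignment table as CSV
#'
#' Inverse of [read_assignment_table()]: writes `Barcode,Assignment` with
#' doublets and negatives serialized as `doublet` / `negative`.
#'
#' @param table An `assignment_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assignment_table <- function(table, path) {
  stopifnot(inherits(table, "assignment_table"))
  out <- data.frame(
    Barcode = table$calls$barcode,
    Assignment = ifelse(table$calls$kind == "singlet",
                        table$calls$label, table$calls$kind),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Binarize an assignment table
#'
#' Converts a table into a barcodes x labels 0/1 matrix: entry `(c, l)` is 1
#' iff `c` is a singlet of label `l`.  Doublet and negative barcodes give
#' all-zero rows.  Rows are sorted lexicographically by barcode; columns
#' default to the sorted distinct singlet labels (an explicit `labels`
#' vector overrides membership and order).
#'
#' @param table An `assignment_table`.
#' @param labels Optional ordered character vector of column labels.
#' @return A base 0/1 matrix with barcode rownames and label colnames.
#' @export
binarize <- function(table, labels = NULL) {
  stopifnot(inherits(table, "assignment_table"))
  if (is.null(labels)) labels <- singlet_names(table)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicated labels requested")
  bc <- sort(table$calls$barcode)
  m <- matrix(0L, nrow = length(bc), ncol = length(labels),
              dimnames = list(bc, labels))
  sing <- table$calls[table$calls$kind == "singlet" &
                        table$calls$label %in% labels, , drop = FALSE]
  if (nrow(sing)) {
    m[cbind(match(sing$barcode, bc), match(sing$label, labels))] <- 1L
  }
  m
}

#' Restrict two binary assignment matrices to their common barcodes
#'
#' Both matrices are reduced to the sorted intersection of their row
#' (barcode) sets, yielding identical row order, which is the precondition
#' of [pairwise_phi()].  Dropped-row counts are reported via [message()].
#'
#' @param a,b Binary assignment matrices (barcode rownames).
#' @return A list with elements `a` and `b`.
#' @export
align_on_common_barcodes <- function(a, b) {
  common <- sort(intersect(rownames(a), rownames(b)))
  if (!length(common)) stop("no barcodes in common between the two matrices")
  da <- nrow(a) - length(common)
  db <- nrow(b) - length(common)
  if (da || db) {
    message(sprintf("align_on_common_barcodes: dropped %d barcode(s) from first, %d from second; %d retained",
                    da, db, length(common)))
  }
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}
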