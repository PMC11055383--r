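#' Joint (rescued) per-cell assignment
#'
#' Combines a hashing and a genetic assignment table with the donor match
#' into one final per-cell identity with provenance.  Only cells that are
#' confidently genetically deconvoluted are eligible to be rescued: for a
#' genetic singlet of a matched donor `d -> h`,
#' \itemize{
#'   \item hashing singlet `h`      -> (singlet `h`, `confirmed`)
#'   \item hashing negative         -> (singlet `h`, `rescued`)
#'   \item hashing singlet `h' != h` or hashing doublet
#'                                  -> (singlet `h`, `conflict`)
#' }
#' A genetic singlet of an unmatched donor keeps its anonymous label
#' (`unmatched_donor`); genetic doublets stay doublets; genetic negatives
#' stay negatives and are never rescued.  Under
#' `conflict_policy = "drop"` conflicting cells are excluded from the
#' final singlets (kind `negative`, provenance still `conflict`).
#'
#' @param hashing_table,genetic_table `assignment_table`s sharing barcodes.
#' @param match A `donor_match` computed from (or compatible with) the two
#'   tables.
#' @param conflict_policy `"genetic"` (default: genetic identity wins,
#'   flagged) or `"drop"`.
#' @return An object of class `joint_assignment`: data.frame with columns
#'   `barcode`, `kind`, `label`, `provenance`, sorted by barcode; cells
#'   outside the barcode intersection are excluded (counts reported via
#'   [message()]).
#' @export
joint_assign <- function(hashing_table, genetic_table, match,
                         conflict_policy = c("genetic", "drop")) {
  stopifnot(inherits(hashing_table, "assignment_table"),
            inherits(genetic_table, "assignment_table"))
  conflict_policy <- match.arg(conflict_policy)
  map <- matched_pairs(match)
  hb <- hashing_table$calls; gb <- genetic_table$calls
  common <- sort(intersect(hb$barcode, gb$barcode))
  if (!length(common)) stop("no barcodes shared between hashing and genetic tables")
  n_drop <- (nrow(hb) - length(common)) + (nrow(gb) - length(common))
  if (n_drop) {
    message(sprintf("joint_assign: %d barcode(s) outside the intersection excluded", n_drop))
  }
  h <- hb[match(common, hb$barcode), ]
  g <- gb[match(common, gb$barcode), ]

  kind <- character(length(common))
  label <- rep(NA_character_, length(common))
  prov <- character(length(common))

  g_sing <- g$kind == "singlet"
  g_matched <- g_sing & g$label %in% names(map)
  hash_of <- rep(NA_character_, length(common))
  hash_of[g_matched] <- unname(map[g$label[g_matched]])

  # genetic doublets / negatives pass through
  kind[g$kind == "doublet"] <- "doublet"; prov[g$kind == "doublet"] <- "doublet"
  kind[g$kind == "negative"] <- "negative"; prov[g$kind == "negative"] <- "negative"

  # genetic singlet, unmatched donor: anonymous label retained
  un <- g_sing & !g_matched
  kind[un] <- "singlet"; label[un] <- g$label[un]; prov[un] <- "unmatched_donor"

  # genetic singlet of matched donor
  conf <- g_matched & h$kind == "singlet" & h$label == hash_of
  resc <- g_matched & h$kind == "negative"
  cfl <- g_matched & !conf & !resc
  kind[g_matched] <- "singlet"
  label[g_matched] <- hash_of[g_matched]
  prov[conf] <- "confirmed"; prov[resc] <- "rescued"; prov[cfl] <- "conflict"
  if (conflict_policy == "drop") {
    kind[cfl] <- "negative"; label[cfl] <- NA_character_
  }

  structure(
    data.frame(barcode = common, kind = kind, label = label,
               provenance = prov, stringsAsFactors = FALSE),
    class = c("joint_assignment", "data.frame"),
    donor_map = map)
}

#' Classification flow summary
#'
#' Counts, for every (hashing label, final label, provenance) triple, how
#' many common barcodes took that path — the tabular form of a Sankey
#' diagram of the rescue step.  Percentages are within each hashing label.
#'
#' @param hashing_table The hashing `assignment_table`.
#' @param joint A `joint_assignment`.
#' @return data.frame with columns `HashingLabel`, `FinalLabel`,
#'   `Provenance`, `Count`, `Percent`.
#' @export
summarize_flows <- function(hashing_table, joint) {
  stopifnot(inherits(hashing_table, "assignment_table"),
            inherits(joint, "joint_assignment"))
  hb <- hashing_table$calls
  h <- hb[match(joint$barcode, hb$barcode), ]
  hl <- ifelse(h$kind == "singlet", h$label, h$kind)
  fl <- ifelse(joint$kind == "singlet", joint$label, joint$kind)
  agg <- stats::aggregate(list(Count = seq_along(hl)),
                          by = list(HashingLabel = hl, FinalLabel = fl,
                                    Provenance = joint$provenance),
                          FUN = length)
  tot <- tapply(agg$Count, agg$HashingLabel, sum)
  agg$Percent <- 100 * agg$Count / as.numeric(tot[agg$HashingLabel])
  agg <- agg[order(agg$HashingLabel, agg$FinalLabel, agg$Provenance), ]
  rownames(agg) <- NULL
  agg
}

#' Rescue and singlet rates
#'
#' @param hashing_table The hashing `assignment_table`.
#' @param joint A `joint_assignment`.
#' @return List with `rescued_fraction` (rescued / hashing negatives among
#'   common barcodes; `NA` when the hashing table has no negatives),
#'   `singlet_fraction` (final singlets / common barcodes),
#'   `n_hashing_negative` and `n_rescued`.
#' @export
rescue_rate <- function(hashing_table, joint) {
  stopifnot(inherits(hashing_table, "assignment_table"),
            inherits(joint, "joint_assignment"))
  hb <- hashing_table$calls
  h <- hb[match(joint$barcode, hb$barcode), ]
  n_neg <- sum(h$kind == "negative")
  n_resc <- sum(joint$provenance == "rescued")
  list(rescued_fraction = if (n_neg) n_resc / n_neg else NA_real_,
       singlet_fraction = mean(joint$kind == "singlet"),
       n_hashing_negative = n_neg,
       n_rescued = n_resc)
}

#' Convert a joint assignment to a plain assignment table
#'
#' @param joint A `joint_assignment`.
#' @param method_name Method name of the resulting table (default
#'   `"rescued"`).
#' @param family Family tag for the table (default `"genetic"`, since the
#'   rescued identities are genetically driven).
#' @return An `assignment_table`.
#' @export
as_assignment_table <- function(joint, method_name = "rescued",
                                family = "genetic") {
  stopifnot(inherits(joint, "joint_assignment"))
  assignment <- ifelse(joint$kind == "singlet", joint$label, joint$kind)
  assignment_table(joint$barcode, assignment, method_name, family)
}

#' Write / read a joint assignment CSV
#'
#' Dialect: `Barcode,Assignment,Provenance`, with doublets and negatives
#' serialized as `doublet` / `negative` in the `Assignment` column.
#'
#' @param joint A `joint_assignment`.
#' @param path CSV path.
#' @return `path` (write) or a `joint_assignment` (read).
#' @export
write_joint_assignment <- function(joint, path) {
  stopifnot(inherits(joint, "joint_assignment"))
  out <- data.frame(
    Barcode = joint$barcode,
    Assignment = ifelse(joint$kind == "singlet", joint$label, joint$kind),
    Provenance = joint$provenance,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_joint_assignment
#' @export
read_joint_assignment <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("Barcode", "Assignment", "Provenance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing required column(s) ", paste(miss, collapse = ", "), " in ", path)
  }
  low <- tolower(df$Assignment)
  kind <- ifelse(low == "doublet", "doublet",
          ifelse(low == "negative", "negative", "singlet"))
  structure(
    data.frame(barcode = df$Barcode, kind = kind,
               label = ifelse(kind == "singlet", df$Assignment, NA_character_),
               provenance = df$Provenance, stringsAsFactors = FALSE),
    class = c("joint_assignment", "data.frame"))
}
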