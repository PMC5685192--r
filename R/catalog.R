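#' XCI status catalogues
#'
#' Prior studies assign X-linked genes one of three inactivation statuses:
#' `escape` (expressed from Xi), `variable` (escape in some
#' lines/individuals only), `inactive` (silenced on Xi). `absent` marks a
#' gene not assessed by a study. These helpers read, derive and merge such
#' catalogues.
#'
#' @name catalog
NULL

xci_statuses <- c("escape", "variable", "inactive", "absent")

#' Categorize a gene from Xi-expressing cell-line counts
#'
#' Somatic-cell-hybrid surveys score, per gene, how many of a panel of Xi
#' hybrids (classically nine) express the gene from Xi. The expressing
#' fraction is cut into three classes: below `t_lo` inactive, at or above
#' `t_hi` escape, otherwise variable. The thresholds default to 2/9 and 7/9,
#' which keep all three classes non-empty on a nine-line panel; they are
#' deliberately configurable because published surveys do not fix them.
#'
#' @param n_expressing_lines,n_lines integers, 0 <= expressing <= total.
#' @param t_lo,t_hi fractions with 0 <= t_lo < t_hi <= 1.
#' @return status string.
#' @export
categorize_from_xi_counts <- function(n_expressing_lines, n_lines,
                                      t_lo = 2 / 9, t_hi = 7 / 9) {
  if (t_lo >= t_hi) stop("config error: need t_lo < t_hi")
  if (any(n_expressing_lines < 0) || any(n_expressing_lines > n_lines))
    stop("require 0 <= n_expressing_lines <= n_lines")
  f <- n_expressing_lines / n_lines
  ifelse(f < t_lo, "inactive", ifelse(f >= t_hi, "escape", "variable"))
}

#' Harmonize two XCI status assignments
#'
#' Merge rule for one gene reported by two studies: equal statuses (or one
#' study absent) keep the defined status; conflicts resolve as
#' escape+variable -> escape, escape+inactive -> variable,
#' inactive+variable -> inactive. Symmetric in its arguments; both-absent is
#' an error.
#'
#' @param status_a,status_b statuses in `{escape, variable, inactive,
#'   absent}` (vectorized).
#' @return combined status vector.
#' @export
harmonize_status <- function(status_a, status_b) {
  chk <- function(s) if (!all(s %in% xci_statuses))
    stop("unknown status: ", paste(setdiff(s, xci_statuses), collapse = ", "))
  chk(status_a); chk(status_b)
  if (any(status_a == "absent" & status_b == "absent"))
    stop("both statuses absent: gene was assessed by neither study")
  one <- function(a, b) {
    if (a == b) return(a)
    if (a == "absent") return(b)
    if (b == "absent") return(a)
    pair <- sort(c(a, b))
    if (identical(pair, c("escape", "variable"))) return("escape")
    if (identical(pair, c("escape", "inactive"))) return("variable")
    if (identical(pair, c("inactive", "variable"))) return("inactive")
    stop("unreachable status pair: ", a, "+", b)
  }
  mapply(one, status_a, status_b, USE.NAMES = FALSE)
}

#' Combine two XCI catalogues
#'
#' Takes the union of genes across two catalogues (data.frames with
#' `gene_id` and `status`; optional `gene_name`, `source`), resolves
#' per-gene conflicts through [harmonize_status()], and reports per-status
#' totals. An optional alias map (named character vector alias -> gene_id)
#' renames list-B genes before matching; aliases that match nothing are
#' reported in the result, never dropped silently.
#'
#' @param list_a,list_b catalogue data.frames; duplicate `gene_id` within a
#'   list is an error.
#' @param aliases optional named character vector mapping alternative names
#'   to canonical `gene_id`s.
#' @return list with `combined` (gene_id, status, source), `counts` (table
#'   of statuses) and `unmatched_aliases`.
#' @export
combine_catalogues <- function(list_a, list_b, aliases = NULL) {
  for (l in list(list_a, list_b)) {
    if (!all(c("gene_id", "status") %in% names(l)))
      stop("catalogues need gene_id and status columns")
    if (anyDuplicated(l$gene_id))
      stop("duplicate gene_id within one catalogue: ",
           paste(unique(l$gene_id[duplicated(l$gene_id)]), collapse = ", "))
  }
  unmatched <- character(0)
  if (!is.null(aliases)) {
    hit <- list_b$gene_id %in% names(aliases)
    mapped <- unname(aliases[list_b$gene_id[hit]])
    known <- mapped %in% c(list_a$gene_id, list_b$gene_id)
    unmatched <- setdiff(unname(aliases), c(list_a$gene_id, mapped))
    list_b$gene_id[hit] <- mapped
    if (anyDuplicated(list_b$gene_id)) stop("alias mapping created duplicate gene_id")
  }
  genes <- union(list_a$gene_id, list_b$gene_id)
  sa <- stats::setNames(list_a$status, list_a$gene_id)[genes]
  sb <- stats::setNames(list_b$status, list_b$gene_id)[genes]
  sa[is.na(sa)] <- "absent"; sb[is.na(sb)] <- "absent"
  status <- harmonize_status(sa, sb)
  src_a <- if (!is.null(list_a$source)) list_a$source[1] else "A"
  src_b <- if (!is.null(list_b$source)) list_b$source[1] else "B"
  source <- ifelse(sa == "absent", src_b,
                   ifelse(sb == "absent", src_a, paste(src_a, src_b, sep = "+")))
  combined <- data.frame(gene_id = genes, status = status, source = source,
                         stringsAsFactors = FALSE, row.names = NULL)
  list(combined = combined,
       counts = table(factor(status, levels = c("escape", "variable", "inactive"))),
       unmatched_aliases = unmatched)
}

#' Read / write catalogue CSV
#'
#' Columns: `gene_id`, optional `gene_name`, `status`, optional `source`.
#' @param path CSV file.
#' @export
read_catalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "status") %in% names(df)))
    stop("catalogue CSV needs gene_id and status columns")
  if (!all(df$status %in% xci_statuses))
    stop("unknown status values in ", path)
  df
}

#' @rdname read_catalog
#' @param catalog catalogue data.frame.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(catalog, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
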