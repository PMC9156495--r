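#' Error-normalised fold change (ENFC)
#'
#' The package's ENFC is the standardized log2 fold change obtained by the
#' delta method: with both group means > 0 and both n >= 2,
#' \deqn{ENFC = log2(mean_case / mean_ref) / SE,}
#' \deqn{SE = (1/ln 2) \sqrt{sd_case^2/(n_case mean_case^2) +
#'   sd_ref^2/(n_ref mean_ref^2)}.}
#' Positive values mean the unit is more abundant in the non-reference
#' (case) group. ENFC is 0 at equal means, shrinks as noise grows, negates
#' under a group swap, and is invariant to rescaling both groups by a common
#' positive factor.
#'
#' @param mean_ref,sd_ref,n_ref Reference-group mean, sample sd (n-1
#'   denominator) and size.
#' @param mean_case,sd_case,n_case Case-group summaries.
#' @return List with \code{enfc} (signed real, \code{NA} when undefined,
#'   \code{+/-Inf} sentinel when both sds are 0), \code{undefined} and
#'   \code{reason}.
#' @details Undefined whenever either group mean is 0 (the log fold change
#'   does not exist) or either n < 2 (no error estimate); such records are
#'   reported with a reason, never silently dropped.
#' @examples
#' enfc(2, 0.2, 5, 4, 0.2, 5)$enfc  # positive: doubled in the case group
#' @export
enfc <- function(mean_ref, sd_ref, n_ref, mean_case, sd_case, n_case) {
  vals <- c(mean_ref, sd_ref, n_ref, mean_case, sd_case, n_case)
  if (anyNA(vals) || any(vals < 0))
    stop("ENFC inputs must be non-negative and non-missing", call. = FALSE)
  if (n_ref < 1 || n_case < 1)
    stop("group sizes must be >= 1", call. = FALSE)
  if (mean_ref == 0)
    return(list(enfc = NA_real_, undefined = TRUE, reason = "zero reference mean"))
  if (mean_case == 0)
    return(list(enfc = NA_real_, undefined = TRUE, reason = "zero case mean"))
  if (n_ref < 2 || n_case < 2)
    return(list(enfc = NA_real_, undefined = TRUE, reason = "fewer than 2 replicates"))
  lfc <- log2(mean_case / mean_ref)
  se <- sqrt(sd_case^2 / (n_case * mean_case^2) +
             sd_ref^2 / (n_ref * mean_ref^2)) / log(2)
  if (se == 0) {
    val <- if (lfc == 0) 0 else sign(lfc) * Inf
    return(list(enfc = val, undefined = FALSE, reason = "zero standard error"))
  }
  list(enfc = lfc / se, undefined = FALSE, reason = NA_character_)
}

# Shared machinery: take a group summary (from summarise_groups), spread
# reference vs case, and compute one ENFC record per (unit, compartment).
enfc_from_summary <- function(summ, reference, network) {
  phen <- sort(unique(summ$phenotype))
  if (!reference %in% phen)
    stop("reference phenotype '", reference, "' not found in data (labels: ",
         paste(phen, collapse = ", "), ")", call. = FALSE)
  case <- setdiff(phen, reference)
  ref_dt <- summ[summ$phenotype == reference,
                 c("unit", "compartment", "n", "mean", "sd")]
  setnames(ref_dt, c("n", "mean", "sd"), c("n_ref", "mean_ref", "sd_ref"))
  case_dt <- summ[summ$phenotype == case,
                  c("unit", "compartment", "n", "mean", "sd")]
  setnames(case_dt, c("n", "mean", "sd"), c("n_case", "mean_case", "sd_case"))
  out <- merge(ref_dt, case_dt, by = c("unit", "compartment"), all = TRUE)
  for (col in c("n_ref", "n_case")) out[is.na(get(col)), (col) := 0L]
  for (col in c("mean_ref", "sd_ref", "mean_case", "sd_case"))
    out[is.na(get(col)), (col) := 0]
  res <- lapply(seq_len(nrow(out)), function(i) {
    r <- out[i]
    if (r$n_ref < 1 || r$n_case < 1)
      return(list(enfc = NA_real_, undefined = TRUE,
                  reason = "group absent from compartment"))
    enfc(r$mean_ref, r$sd_ref, r$n_ref, r$mean_case, r$sd_case, r$n_case)
  })
  out[, enfc := vapply(res, function(r) r$enfc, 0)]
  out[, undefined := vapply(res, function(r) r$undefined, TRUE)]
  out[, reason := vapply(res, function(r) as.character(r$reason), "")]
  out[, compartment := factor(compartment, levels = network$compartments)]
  out <- out[order(lipid_order(unit))]
  setorderv(out, "compartment")
  out[, compartment := as.character(compartment)]
  setcolorder(out, c("unit", "compartment",
                     "mean_ref", "sd_ref", "n_ref",
                     "mean_case", "sd_case", "n_case",
                     "enfc", "undefined", "reason"))
  out[]
}

#' Class-level ENFC across compartments
#'
#' One ENFC record per (head group, compartment). Class values are per-sample
#' sums of the class's species (absent species contribute 0), summarised per
#' group and passed to \code{\link{enfc}}.
#'
#' @param tbl An \code{\link{abundance_table}}.
#' @param reference The reference phenotype label; ENFC sign is relative to
#'   it (positive = higher in the other, "case", group).
#' @return \code{data.table} of ENFC records ordered by compartment
#'   (network order) then class.
#' @export
class_enfc <- function(tbl, reference) {
  stopifnot(inherits(tbl, "abundance_table"))
  summ <- summarise_groups(tbl, level = "class")
  enfc_from_summary(summ, reference, at_network(tbl))
}

#' Species-level ENFC panel for a subclass
#'
#' Restricts species-level ENFC to a selection: either a subclass tag
#' (\code{"DNL_MARKER"}, \code{"PUFA"}, \code{"OTHER"}) resolved against the
#' table's tagged panel, or an explicit vector of species names.
#'
#' @param tbl An \code{\link{abundance_table}}.
#' @param selector Tag name or character vector of lipid names.
#' @param reference Reference phenotype label.
#' @return \code{data.table} of ENFC records, ordered by compartment then
#'   species, with a \code{tags} column.
#' @export
subclass_panel <- function(tbl, selector, reference) {
  stopifnot(inherits(tbl, "abundance_table"))
  panel <- at_panel(tbl)
  if (length(selector) == 1L &&
      selector %in% c("DNL_MARKER", "PUFA", "OTHER")) {
    species <- panel$name[vapply(strsplit(panel$tags, ";", fixed = TRUE),
                                 function(tg) selector %in% tg, TRUE)]
  } else {
    canon <- vapply(selector, function(nm)
      render_lipid_name(parse_lipid_name(nm, warn_unknown_head = FALSE)), "")
    species <- intersect(panel$name, canon)
  }
  if (length(species) == 0L)
    stop("selector '", paste(selector, collapse = ", "),
         "' matches no species in the panel", call. = FALSE)
  summ <- summarise_groups(tbl, level = "species")
  out <- enfc_from_summary(summ[summ$unit %in% species, ],
                           reference, at_network(tbl))
  out[, tags := panel$tags[match(unit, panel$name)]]
  out[]
}
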