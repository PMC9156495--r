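#' Call presence of lipids per group
#'
#' Binarizes detection: a lipid counts as present in a (compartment,
#' phenotype) group when its signal is strictly positive in at least
#' \code{threshold_percent}\% of that group's samples. The comparison is done
#' in integer arithmetic, \code{100 * detected_count >= threshold * n}, so
#' e.g. 2 of 3 samples (66.7\%) passes the default 66\% threshold with no
#' floating-point ambiguity. Signals that are exactly 0 are "not detected";
#' there is no epsilon floor.
#'
#' @param tbl A validated \code{\link{abundance_table}}.
#' @param threshold_percent Integer in (0, 100]; default 66.
#' @return A \code{presence_map}: a \code{data.table} with one row per
#'   (lipid, compartment, phenotype) for every lipid observed anywhere in the
#'   table, with columns \code{detected_count}, \code{n}, \code{fraction},
#'   \code{present}; attributes carry the network, phenotypes, lipid panel
#'   and threshold.
#' @export
call_presence <- function(tbl, threshold_percent = 66L) {
  stopifnot(inherits(tbl, "abundance_table"))
  thr <- as.integer(threshold_percent)
  if (is.na(thr) || thr <= 0L || thr > 100L)
    stop("threshold_percent must be an integer in (0, 100]", call. = FALSE)
  dt <- as.data.table(tbl)
  panel <- at_panel(tbl)
  sizes <- group_sizes(tbl)
  det <- dt[signal > 0, list(detected_count = .N),
            by = c("lipid", "compartment", "phenotype")]
  grid <- sizes[, list(lipid = panel$name), by = c("phenotype", "compartment", "n")]
  pm <- merge(grid, det, by = c("lipid", "compartment", "phenotype"), all.x = TRUE)
  pm[is.na(detected_count), detected_count := 0L]
  pm[, fraction := detected_count / n]
  pm[, present := n > 0L & 100L * detected_count >= thr * n]
  net <- at_network(tbl)
  pm[, compartment := factor(compartment, levels = net$compartments)]
  pm <- pm[order(lipid_order(lipid))]
  setorderv(pm, c("compartment", "phenotype"))
  pm[, compartment := as.character(compartment)]
  setcolorder(pm, c("lipid", "compartment", "phenotype",
                    "detected_count", "n", "fraction", "present"))
  setattr(pm, "network", net)
  setattr(pm, "panel", panel)
  setattr(pm, "phenotypes", at_phenotypes(tbl))
  setattr(pm, "threshold", thr)
  setattr(pm, "class", c("presence_map", class(pm)))
  pm[]
}

#' @importFrom data.table setcolorder
NULL

# Construct a presence_map directly from a logical presence statement
# (used by the synthetic-data ground truth; bypasses sampling entirely).
presence_map_from_logical <- function(present_dt, network, panel, phenotypes,
                                      n = 1L, threshold = 66L) {
  pm <- as.data.table(present_dt)
  stopifnot(all(c("lipid", "compartment", "phenotype", "present") %in% names(pm)))
  pm[, `:=`(n = as.integer(n),
            detected_count = ifelse(present, as.integer(n), 0L))]
  pm[, fraction := detected_count / n]
  pm[, compartment := factor(compartment, levels = network$compartments)]
  pm <- pm[order(lipid_order(lipid))]
  setorderv(pm, c("compartment", "phenotype"))
  pm[, compartment := as.character(compartment)]
  setcolorder(pm, c("lipid", "compartment", "phenotype",
                    "detected_count", "n", "fraction", "present"))
  setattr(pm, "network", network)
  setattr(pm, "panel", panel)
  setattr(pm, "phenotypes", phenotypes)
  setattr(pm, "threshold", as.integer(threshold))
  setattr(pm, "class", c("presence_map", class(pm)))
  pm[]
}

# Named logical vector over the full panel: present at a single compartment.
node_presence_vector <- function(pm, compartment, phenotype) {
  panel <- at_panel(pm)
  dt <- as.data.table(pm)
  idx <- dt$compartment == compartment & dt$phenotype == phenotype
  sub <- dt[idx, ]
  out <- setNames(logical(nrow(panel)), panel$name)
  out[sub$lipid] <- sub$present
  out
}

#' Presence on an axis
#'
#' A lipid is present on an axis for a phenotype when it is present at both
#' endpoint compartments. Lipids absent from the table are not axis-present.
#'
#' @param pm A \code{presence_map} from \code{\link{call_presence}}.
#' @param axis Character vector of two compartment ids (either order).
#' @param phenotype One of the two group labels.
#' @return Named logical vector over the lipid panel.
#' @export
axis_presence <- function(pm, axis, phenotype) {
  stopifnot(inherits(pm, "presence_map"))
  net <- attr(pm, "network", exact = TRUE)
  match_axis(net, axis)
  if (!phenotype %in% attr(pm, "phenotypes", exact = TRUE))
    stop("unknown phenotype: ", phenotype, call. = FALSE)
  node_presence_vector(pm, axis[1], phenotype) &
    node_presence_vector(pm, axis[2], phenotype)
}
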