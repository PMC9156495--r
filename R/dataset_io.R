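#' Construct an abundance table
#'
#' The canonical container for per-sample lipid signals: long-format records
#' of (sample, phenotype, compartment, lipid, signal) bound to a
#' \code{\link{traffic_network}}. Missing (sample, compartment, lipid)
#' combinations are semantically signal = 0 (non-detection), not
#' missing-at-random.
#'
#' @param records A data.frame with columns \code{sample_id},
#'   \code{phenotype}, \code{compartment}, \code{lipid}, \code{signal}.
#' @param network The bound \code{\link{traffic_network}}.
#' @param policy \code{\link{tagging_policy}} used to annotate the panel.
#' @param warn_unknown_head Passed to the name parser.
#' @return An \code{abundance_table}: a \code{data.table} of validated
#'   records (lipids canonicalised) with attributes \code{network},
#'   \code{panel} (the species registry with subclass tags) and
#'   \code{phenotypes} (the two group labels, sorted).
#' @details Validation enforces: exactly two phenotype labels; all
#'   compartments declared in the network; signals non-negative; at most one
#'   record per (sample, compartment, lipid). Violations are reported with
#'   the offending row numbers of \code{records}.
#' @export
abundance_table <- function(records, network, policy = tagging_policy(),
                            warn_unknown_head = TRUE) {
  stopifnot(inherits(network, "traffic_network"))
  required <- c("sample_id", "phenotype", "compartment", "lipid", "signal")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("abundance table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dt <- as.data.table(records)[, required, with = FALSE]
  dt[, `:=`(sample_id = as.character(sample_id),
            phenotype = as.character(phenotype),
            compartment = as.character(compartment),
            lipid = as.character(lipid),
            signal = as.numeric(signal))]
  if (nrow(dt) == 0L)
    stop("abundance table has no records", call. = FALSE)

  phen <- sort(unique(dt$phenotype))
  if (length(phen) != 2L)
    stop(sprintf("exactly two phenotype labels required, found %d: %s",
                 length(phen), paste(phen, collapse = ", ")), call. = FALSE)
  bad_comp <- !(dt$compartment %in% network$compartments)
  if (any(bad_comp))
    stop("unknown compartment(s) ",
         paste(unique(dt$compartment[bad_comp]), collapse = ", "),
         " at row(s) ", paste(utils::head(which(bad_comp), 5), collapse = ", "),
         call. = FALSE)
  bad_sig <- is.na(dt$signal) | dt$signal < 0
  if (any(bad_sig))
    stop("negative or missing signal at row(s) ",
         paste(utils::head(which(bad_sig), 5), collapse = ", "), call. = FALSE)

  panel <- build_lipid_panel(unique(dt$lipid), policy = policy,
                             warn_unknown_head = warn_unknown_head)
  dt[, lipid := panel$name[match(lipid, panel$raw_name)]]

  dup <- duplicated(dt, by = c("sample_id", "compartment", "lipid"))
  if (any(dup))
    stop("duplicate (sample, compartment, lipid) record at row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "), call. = FALSE)

  # A phenotype label must be constant within a sample id.
  ps <- unique(dt[, c("sample_id", "phenotype")])
  if (anyDuplicated(ps$sample_id))
    stop("sample id(s) assigned to both phenotypes: ",
         paste(unique(ps$sample_id[duplicated(ps$sample_id)]), collapse = ", "),
         call. = FALSE)

  setorderv(dt, c("phenotype", "compartment", "sample_id"))
  dt <- dt[order(lipid_order(lipid))]
  setattr(dt, "network", network)
  setattr(dt, "panel", panel)
  setattr(dt, "phenotypes", phen)
  setattr(dt, "class", c("abundance_table", class(dt)))
  dt[]
}

#' @importFrom data.table setattr
NULL

#' Read an abundance table from delimited text
#'
#' Reads a UTF-8 comma- or tab-delimited file (delimiter sniffed from the
#' header line) with columns \code{sample_id}, \code{phenotype},
#' \code{compartment}, \code{lipid}, \code{signal}, validates it against the
#' network and returns an \code{\link{abundance_table}}.
#'
#' @param path Path to the delimited file.
#' @inheritParams abundance_table
#' @return An \code{abundance_table}.
#' @export
read_abundance_table <- function(path, network, policy = tagging_policy(),
                                 warn_unknown_head = TRUE) {
  if (!file.exists(path))
    stop("abundance file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L || !nzchar(header))
    stop("abundance file is empty: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  dt <- fread(path, sep = sep, header = TRUE, colClasses = list(
    character = c("sample_id", "phenotype", "compartment", "lipid")),
    encoding = "UTF-8")
  abundance_table(dt, network, policy = policy,
                  warn_unknown_head = warn_unknown_head)
}

#' Write an abundance table to delimited text
#'
#' Round-trips losslessly through \code{\link{read_abundance_table}} for all
#' fields.
#'
#' @param tbl An \code{abundance_table}.
#' @param path Output path; extension \code{.csv} selects comma, anything
#'   else tab.
#' @return \code{path}, invisibly.
#' @export
write_abundance_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "abundance_table"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  fwrite(as.data.table(tbl)[, c("sample_id", "phenotype", "compartment",
                                "lipid", "signal"), with = FALSE],
         path, sep = sep)
  invisible(path)
}

at_network <- function(tbl) attr(tbl, "network", exact = TRUE)
at_panel <- function(tbl) attr(tbl, "panel", exact = TRUE)
at_phenotypes <- function(tbl) attr(tbl, "phenotypes", exact = TRUE)

# Distinct samples per (phenotype, compartment): the group sizes n used by
# presence calling and group summaries. Group sizes may differ between
# compartments (tissue dropout is tolerated).
group_sizes <- function(tbl) {
  dt <- as.data.table(tbl)
  out <- unique(dt[, c("phenotype", "compartment", "sample_id")])
  out[, list(n = .N), by = c("phenotype", "compartment")]
}

#' Summarise abundances by group
#'
#' Per (unit, compartment, phenotype) sample mean and standard deviation
#' (n-1 denominator), computed over all of the group's samples with absent
#' records contributing 0. At \code{level = "class"} each sample's class
#' value is first the sum of signals over species sharing the head group
#' (sum within sample first, then summarise).
#'
#' @param tbl An \code{\link{abundance_table}}.
#' @param level \code{"species"} or \code{"class"}.
#' @return A \code{data.table} with columns \code{unit}, \code{compartment},
#'   \code{phenotype}, \code{n}, \code{mean}, \code{sd}, \code{degenerate}
#'   (\code{TRUE} when n = 1, where sd is reported as 0).
#' @export
summarise_groups <- function(tbl, level = c("species", "class")) {
  stopifnot(inherits(tbl, "abundance_table"))
  level <- match.arg(level)
  dt <- as.data.table(tbl)
  panel <- at_panel(tbl)
  sizes <- group_sizes(tbl)
  samples <- unique(dt[, c("phenotype", "compartment", "sample_id")])

  if (level == "class") {
    dt <- merge(dt, panel[, c("name", "head_group")],
                by.x = "lipid", by.y = "name")
    per_sample <- dt[, list(value = sum(signal)),
                     by = c("head_group", "phenotype", "compartment", "sample_id")]
    setnames(per_sample, "head_group", "unit")
    units <- unique(panel$head_group)
  } else {
    per_sample <- dt[, c("lipid", "phenotype", "compartment", "sample_id", "signal")]
    setnames(per_sample, c("lipid", "signal"), c("unit", "value"))
    units <- panel$name
  }
  # Expand to the full grid of (unit x group samples); absent records are 0.
  grid <- samples[, list(unit = units), by = c("phenotype", "compartment", "sample_id")]
  full <- merge(grid, per_sample,
                by = c("unit", "phenotype", "compartment", "sample_id"),
                all.x = TRUE)
  full[is.na(value), value := 0]
  out <- full[, list(n = .N, mean = mean(value),
                     sd = if (.N > 1L) sd(value) else 0),
              by = c("unit", "compartment", "phenotype")]
  out[, degenerate := n == 1L]
  net <- at_network(tbl)
  out[, compartment := factor(compartment, levels = net$compartments)]
  out <- out[order(lipid_order(unit))]
  setorderv(out, c("compartment", "phenotype"))
  out[, compartment := as.character(compartment)]
  out[]
}
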