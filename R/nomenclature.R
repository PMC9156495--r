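#' @importFrom data.table data.table := setkeyv setorderv as.data.table rbindlist fwrite fread copy setnames CJ
#' @importFrom stats rlnorm runif rhyper sd setNames
#' @importFrom utils packageVersion
NULL

# Head groups we expect to see in shotgun lipidomics class shorthand.
# The vocabulary is open: unknown alphabetic tokens parse with a warning.
KNOWN_HEAD_GROUPS <- c("TG", "DG", "PC", "PE", "PI", "PS", "PG", "PA",
                       "SM", "CE", "LPC", "LPE")

#' Parse a lipid shorthand name
#'
#' Parses class-level lipid shorthand of the form \code{HEAD(C:D)}, e.g.
#' \code{"TG(52:7)"} or \code{"PI(38:6)"}, where \code{C} is the total number
#' of acyl carbons and \code{D} the total number of double bonds. Only plain
#' \code{C:D} shorthand is accepted; ether, odd-chain-marker or adduct
#' notations such as \code{"PC(O-34:1)"} are rejected rather than coerced.
#'
#' @param name A single character string.
#' @param warn_unknown_head Warn when the head group is outside the known
#'   vocabulary (\code{TG, DG, PC, PE, PI, PS, PG, PA, SM, CE, LPC, LPE}).
#' @return An object of class \code{lipid_species}: a list with fields
#'   \code{raw_name}, \code{head_group}, \code{carbons}, \code{double_bonds}
#'   and \code{tags} (empty until \code{\link{tag_species}} is applied).
#' @examples
#' parse_lipid_name("TG(52:7)")
#' parse_lipid_name(" PI(38:6) ")$carbons
#' @seealso \code{\link{expand_name_list}}, \code{\link{tag_species}}
#' @export
parse_lipid_name <- function(name, warn_unknown_head = TRUE) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("lipid name must be a single character string", call. = FALSE)
  stripped <- trimws(name)
  m <- regmatches(stripped,
                  regexec("^([A-Za-z]+)\\(\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*\\)$",
                          stripped))[[1]]
  if (length(m) != 4L)
    stop(sprintf("malformed lipid name: '%s' (expected HEAD(C:D) shorthand)",
                 name), call. = FALSE)
  head_group <- m[2]
  carbons <- suppressWarnings(as.integer(m[3]))
  double_bonds <- suppressWarnings(as.integer(m[4]))
  if (is.na(carbons) || is.na(double_bonds))
    stop(sprintf("malformed lipid name: '%s' (carbon/double-bond counts must be integers)",
                 name), call. = FALSE)
  if (carbons < 2L)
    stop(sprintf("invalid lipid name '%s': carbons must be >= 2", name),
         call. = FALSE)
  if (warn_unknown_head && !(head_group %in% KNOWN_HEAD_GROUPS))
    warning(sprintf("head group '%s' is outside the known vocabulary (%s)",
                    head_group, paste(KNOWN_HEAD_GROUPS, collapse = ", ")),
            call. = FALSE)
  structure(list(raw_name = name,
                 head_group = head_group,
                 carbons = carbons,
                 double_bonds = double_bonds,
                 tags = character(0)),
            class = "lipid_species")
}

#' Render a lipid species as canonical shorthand
#'
#' @param x A \code{lipid_species}, or a head group string when \code{carbons}
#'   and \code{double_bonds} are given.
#' @param carbons,double_bonds Integer counts, used when \code{x} is a string.
#' @return Canonical \code{"HEAD(C:D)"} string; round-trips through
#'   \code{\link{parse_lipid_name}}.
#' @export
render_lipid_name <- function(x, carbons = NULL, double_bonds = NULL) {
  if (inherits(x, "lipid_species"))
    return(sprintf("%s(%d:%d)", x$head_group, x$carbons, x$double_bonds))
  sprintf("%s(%d:%d)", x, as.integer(carbons), as.integer(double_bonds))
}

#' @export
print.lipid_species <- function(x, ...) {
  cat(sprintf("<lipid_species> %s  [head=%s C=%d DB=%d]",
              render_lipid_name(x), x$head_group, x$carbons, x$double_bonds))
  if (length(x$tags)) cat("  tags:", paste(x$tags, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Expand a grouped lipid name list
#'
#' Results in lipidomics are often written as grouped lists sharing a head
#' group, e.g. \code{"PI(36:2, 36:3)"}. This expands such a string into one
#' \code{lipid_species} per \code{C:D} pair.
#'
#' @param name String of the form \code{HEAD(C1:D1, C2:D2, ...)}.
#' @inheritParams parse_lipid_name
#' @return List of \code{lipid_species}, all sharing the head group.
#' @examples
#' expand_name_list("PI(36:2, 36:3)")
#' @export
expand_name_list <- function(name, warn_unknown_head = TRUE) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    stop("lipid name must be a single character string", call. = FALSE)
  stripped <- trimws(name)
  m <- regmatches(stripped, regexec("^([A-Za-z]+)\\((.*)\\)$", stripped))[[1]]
  if (length(m) != 3L)
    stop(sprintf("malformed lipid name list: '%s'", name), call. = FALSE)
  head_group <- m[2]
  pairs <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
  if (length(pairs) == 0L || any(!nzchar(pairs)))
    stop(sprintf("malformed lipid name list: '%s' (empty C:D pair)", name),
         call. = FALSE)
  lapply(pairs, function(p)
    parse_lipid_name(sprintf("%s(%s)", head_group, p),
                     warn_unknown_head = warn_unknown_head))
}

#' Tagging policy for lipid subclasses
#'
#' Builds the policy that assigns subclass tags to parsed species. Two
#' subclasses drive the downstream panels:
#' \describe{
#'   \item{\code{DNL_MARKER}}{Triglycerides indicative of de novo lipogenesis:
#'     short, (near-)saturated TGs. Default rule: head group \code{TG} with
#'     \code{double_bonds <= dnl_max_db} and \code{carbons <= dnl_max_carbons},
#'     plus an explicit override list.}
#'   \item{\code{PUFA}}{Species carrying polyunsaturated fatty acids. Default
#'     rule: \code{double_bonds >= pufa_min_db_tg} for TGs and
#'     \code{>= pufa_min_db_other} for all other head groups (phospholipids
#'     motivate the lower cutoff).}
#' }
#' Species meeting neither rule are tagged \code{OTHER}. Under the default
#' policy the two rules are disjoint for every species.
#'
#' @param dnl_max_db,dnl_max_carbons DNL rule cutoffs (defaults 1 and 50).
#' @param dnl_explicit Character vector of canonical names always tagged
#'   \code{DNL_MARKER} (TG only).
#' @param pufa_min_db_tg,pufa_min_db_other PUFA double-bond cutoffs
#'   (defaults 6 and 4).
#' @return An object of class \code{tagging_policy}.
#' @export
tagging_policy <- function(dnl_max_db = 1L,
                           dnl_max_carbons = 50L,
                           dnl_explicit = c("TG(44:0)", "TG(46:0)", "TG(48:0)",
                                            "TG(48:1)", "TG(50:0)", "TG(50:1)"),
                           pufa_min_db_tg = 6L,
                           pufa_min_db_other = 4L) {
  stopifnot(dnl_max_db >= 0L, dnl_max_carbons >= 2L,
            pufa_min_db_tg >= 1L, pufa_min_db_other >= 1L)
  structure(list(dnl_max_db = as.integer(dnl_max_db),
                 dnl_max_carbons = as.integer(dnl_max_carbons),
                 dnl_explicit = as.character(dnl_explicit),
                 pufa_min_db_tg = as.integer(pufa_min_db_tg),
                 pufa_min_db_other = as.integer(pufa_min_db_other)),
            class = "tagging_policy")
}

#' Tag a lipid species with subclass labels
#'
#' Tags are a pure function of (head group, carbons, double bonds) and the
#' policy; tagging is deterministic and idempotent. \code{DNL_MARKER} is only
#' ever applied to TGs.
#'
#' @param sp A \code{lipid_species}.
#' @param policy A \code{\link{tagging_policy}}.
#' @return The species with its \code{tags} field populated (a subset of
#'   \code{DNL_MARKER}, \code{PUFA}; or \code{OTHER} when neither applies).
#' @examples
#' tag_species(parse_lipid_name("TG(46:0)"))$tags
#' tag_species(parse_lipid_name("TG(58:11)"))$tags
#' @export
tag_species <- function(sp, policy = tagging_policy()) {
  stopifnot(inherits(sp, "lipid_species"), inherits(policy, "tagging_policy"))
  canon <- render_lipid_name(sp)
  tags <- character(0)
  if (sp$head_group == "TG" &&
      ((sp$double_bonds <= policy$dnl_max_db &&
        sp$carbons <= policy$dnl_max_carbons) ||
       canon %in% policy$dnl_explicit))
    tags <- c(tags, "DNL_MARKER")
  min_db <- if (sp$head_group == "TG") policy$pufa_min_db_tg else policy$pufa_min_db_other
  if (sp$double_bonds >= min_db)
    tags <- c(tags, "PUFA")
  if (length(tags) == 0L) tags <- "OTHER"
  sp$tags <- tags
  sp
}

# Canonical ordering key: head group (alphabetical), then carbons, then
# double bonds. Used everywhere output ordering must be deterministic.
lipid_order <- function(names) {
  parts <- regmatches(names, regexec("^([A-Za-z]+)\\(([0-9]+):([0-9]+)\\)$", names))
  head <- vapply(parts, function(p) if (length(p) == 4L) p[2] else NA_character_, "")
  c_n <- vapply(parts, function(p) if (length(p) == 4L) as.integer(p[3]) else NA_integer_, 1L)
  d_n <- vapply(parts, function(p) if (length(p) == 4L) as.integer(p[4]) else NA_integer_, 1L)
  order(head, c_n, d_n, names)
}

# Build a species registry (one row per canonical name) with tags applied.
build_lipid_panel <- function(names, policy = tagging_policy(),
                              warn_unknown_head = TRUE) {
  uniq <- unique(names)
  sps <- lapply(uniq, function(nm)
    tag_species(parse_lipid_name(nm, warn_unknown_head = warn_unknown_head),
                policy = policy))
  dt <- data.table(
    raw_name = uniq,
    name = vapply(sps, render_lipid_name, ""),
    head_group = vapply(sps, `[[`, "", "head_group"),
    carbons = vapply(sps, `[[`, 1L, "carbons"),
    double_bonds = vapply(sps, `[[`, 1L, "double_bonds"),
    tags = vapply(sps, function(s) paste(s$tags, collapse = ";"), "")
  )
  dup <- dt$name[duplicated(dt$name)]
  if (length(dup))
    stop("lipid names are not unique after canonicalisation: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  dt[lipid_order(dt$name)]
}
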