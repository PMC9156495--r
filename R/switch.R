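#' Classify lipids at a network node
#'
#' At a compartment, a lipid present in both phenotypes is A-type; present in
#' exactly one phenotype it is B-type, attributed to that phenotype; present
#' in neither it is omitted.
#'
#' @param pm A \code{presence_map}.
#' @param compartment A compartment id of the bound network.
#' @return \code{data.table} with columns \code{lipid}, \code{type}
#'   (\code{"A"}/\code{"B"}) and \code{phenotype} (\code{NA} for A-type).
#' @export
classify_node <- function(pm, compartment) {
  stopifnot(inherits(pm, "presence_map"))
  net <- attr(pm, "network", exact = TRUE)
  if (!compartment %in% net$compartments)
    stop("unknown compartment: ", compartment, call. = FALSE)
  phen <- attr(pm, "phenotypes", exact = TRUE)
  classify_vectors(node_presence_vector(pm, compartment, phen[1]),
                   node_presence_vector(pm, compartment, phen[2]),
                   phen)
}

#' Classify lipids on a network axis
#'
#' Same A/B rule as \code{\link{classify_node}}, applied to axis presence
#' (present at both endpoint compartments).
#'
#' @param pm A \code{presence_map}.
#' @param axis Character vector of two compartment ids.
#' @return As \code{\link{classify_node}}.
#' @export
classify_axis <- function(pm, axis) {
  stopifnot(inherits(pm, "presence_map"))
  phen <- attr(pm, "phenotypes", exact = TRUE)
  classify_vectors(axis_presence(pm, axis, phen[1]),
                   axis_presence(pm, axis, phen[2]),
                   phen)
}

classify_vectors <- function(p1, p2, phen) {
  lipids <- names(p1)
  keep <- p1 | p2
  data.table(lipid = lipids[keep],
             type = ifelse(p1[keep] & p2[keep], "A", "B"),
             phenotype = ifelse(p1[keep] & p2[keep], NA_character_,
                                ifelse(p1[keep], phen[1], phen[2])))
}

#' Find ubiquitous (U-type) lipids
#'
#' A lipid is U-type for a phenotype when it is present at every compartment
#' of the network under that phenotype; attribution may be to one or both
#' phenotypes. U-labelling is network-wide and does not remove the lipid
#' from node/axis A/B lists.
#'
#' @param pm A \code{presence_map}.
#' @param network The \code{\link{traffic_network}}; defaults to the one
#'   bound to \code{pm}.
#' @return \code{data.table} with columns \code{lipid}, \code{phenotype}
#'   (one row per attribution).
#' @export
find_ubiquitous <- function(pm, network = NULL) {
  stopifnot(inherits(pm, "presence_map"))
  if (is.null(network)) network <- attr(pm, "network", exact = TRUE)
  phen <- attr(pm, "phenotypes", exact = TRUE)
  panel <- at_panel(pm)
  out <- list()
  for (g in phen) {
    everywhere <- rep(TRUE, nrow(panel))
    for (comp in network$compartments)
      everywhere <- everywhere & node_presence_vector(pm, comp, g)
    if (any(everywhere))
      out[[g]] <- data.table(lipid = panel$name[everywhere], phenotype = g)
  }
  if (length(out) == 0L)
    return(data.table(lipid = character(0), phenotype = character(0)))
  rbindlist(out)
}

#' Run the full switch analysis
#'
#' Classifies every lipid as A- or B-type at every scope (each network node
#' and each axis), finds network-wide U-type lipids per phenotype, and
#' attaches a Jaccard-Tanimoto comparison of the two phenotypes' presence
#' vectors (over the full lipid panel) at every scope. Per-scope permutation
#' seeds are derived deterministically from \code{jparams$seed}.
#'
#' @param pm A \code{presence_map} from \code{\link{call_presence}}.
#' @param network The \code{\link{traffic_network}}; defaults to the bound one.
#' @param jparams A \code{\link{jaccard_params}}.
#' @return A \code{switch_report}: list with \code{types} (scope, scope_kind,
#'   lipid, type, phenotype), \code{ubiquitous} (lipid, phenotype),
#'   \code{jaccard} (scope, scope_kind, J, p, counts, flags, params) and the
#'   network. Scopes are ordered nodes first, then axes, both in network
#'   declaration order; lipids by head group, carbons, double bonds.
#' @export
run_switch <- function(pm, network = NULL, jparams) {
  stopifnot(inherits(pm, "presence_map"), inherits(jparams, "jaccard_params"))
  if (is.null(network)) network <- attr(pm, "network", exact = TRUE)
  phen <- attr(pm, "phenotypes", exact = TRUE)

  scopes <- data.table(
    scope = c(network$compartments,
              if (nrow(network$axes)) apply(network$axes, 1, axis_label)),
    scope_kind = c(rep("node", length(network$compartments)),
                   rep("axis", nrow(network$axes)))
  )

  types <- vector("list", nrow(scopes))
  jacc <- vector("list", nrow(scopes))
  for (i in seq_len(nrow(scopes))) {
    kind <- scopes$scope_kind[i]
    if (kind == "node") {
      comp <- scopes$scope[i]
      cls <- classify_node(pm, comp)
      v1 <- node_presence_vector(pm, comp, phen[1])
      v2 <- node_presence_vector(pm, comp, phen[2])
    } else {
      axis <- network$axes[i - length(network$compartments), ]
      cls <- classify_axis(pm, axis)
      v1 <- axis_presence(pm, axis, phen[1])
      v2 <- axis_presence(pm, axis, phen[2])
    }
    # Deterministic per-scope seed; kept well below 2^31.
    scope_seed <- (jparams$seed + 7919L * i) %% 2147483647L
    jp <- jaccard_params(jparams$B_permutations, seed = scope_seed,
                         alternative = jparams$alternative)
    jr <- jaccard_test(v1, v2, jp)
    types[[i]] <- if (nrow(cls)) cbind(scopes[i], cls) else NULL
    jacc[[i]] <- data.table(scope = scopes$scope[i],
                            scope_kind = kind,
                            J = jr$J, p = jr$p,
                            n_intersection = jr$n_intersection,
                            n_union = jr$n_union,
                            uninformative = jr$uninformative,
                            B_permutations = jp$B_permutations,
                            seed = jp$seed,
                            alternative = jp$alternative)
  }
  structure(list(types = rbindlist(types),
                 ubiquitous = find_ubiquitous(pm, network),
                 jaccard = rbindlist(jacc),
                 network = network,
                 phenotypes = phen,
                 params = jparams),
            class = "switch_report")
}

#' @export
print.switch_report <- function(x, ...) {
  tallies <- x$types[, list(A = sum(type == "A"), B = sum(type == "B")),
                     by = c("scope", "scope_kind")]
  cat(sprintf("<switch_report> %d scopes (%d nodes, %d axes), %d U-type attributions\n",
              nrow(tallies), sum(tallies$scope_kind == "node"),
              sum(tallies$scope_kind == "axis"), nrow(x$ubiquitous)))
  print(tallies)
  invisible(x)
}

# Convenience accessor: B-type lipids at one scope for one phenotype.
#' Extract B-type lipids at a scope
#'
#' @param report A \code{switch_report}.
#' @param scope Scope label: a compartment id or an axis label
#'   (\code{"a-b"} in network declaration order).
#' @param phenotype Optional phenotype filter.
#' @return Character vector of lipid names.
#' @export
b_type_lipids <- function(report, scope, phenotype = NULL) {
  stopifnot(inherits(report, "switch_report"))
  tt <- as.data.frame(report$types)
  sub <- tt[tt$scope == scope & tt$type == "B", ]
  if (!is.null(phenotype)) sub <- sub[!is.na(sub$phenotype) & sub$phenotype == phenotype, ]
  sub$lipid
}
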