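#' Default synthetic lipid panel
#'
#' A deterministic panel of 108 species over the four most populous head
#' groups (TG, PC, PE, PI), spanning C30-C60 and 0-12 double bonds, built to
#' resemble a typical tissue lipidomics identification list (the source
#' design identifies up to ~220 variables; ~100 is a comfortable desk-scale
#' default). Includes the saturated short TGs that mark de novo lipogenesis
#' and the high double-bond PUFA species the analysis highlights.
#'
#' @return Character vector of canonical lipid names.
#' @export
default_lipid_panel <- function() {
  tg <- c(outer(seq(44L, 60L, 2L), c(0L, 1L, 2L, 5L, 7L),
                function(c, d) sprintf("TG(%d:%d)", c, d)),
          "TG(58:11)", "TG(60:10)", "TG(60:11)", "TG(60:12)")
  pc <- c(outer(seq(30L, 38L, 2L), c(0L, 1L, 2L, 4L),
                function(c, d) sprintf("PC(%d:%d)", c, d)),
          "PC(36:6)")
  pe <- c(outer(seq(34L, 40L, 2L), c(1L, 2L, 4L, 6L),
                function(c, d) sprintf("PE(%d:%d)", c, d)),
          "PE(40:7)")
  pi_ <- c(outer(seq(32L, 40L, 2L), c(1L, 2L, 3L, 4L),
                 function(c, d) sprintf("PI(%d:%d)", c, d)),
           "PI(38:6)")
  nm <- c(tg, pc, pe, pi_)
  nm[lipid_order(nm)]
}

#' Default per-class log-abundance baselines
#'
#' Log-normal baselines per head group (meanlog in log arbitrary units,
#' sdlog ~ coefficient of variation). TG is the most abundant class in
#' tissue homogenates, followed by PC, PE and PI; the default within-group
#' CV of ~0.3 is typical of processed LC-MS intensities.
#'
#' @return data.frame with columns \code{head_group}, \code{log_mean},
#'   \code{log_sd}.
#' @export
default_class_baselines <- function() {
  data.frame(head_group = c("TG", "PC", "PE", "PI"),
             log_mean = c(7, 6.5, 6, 5.5),
             log_sd = rep(0.3, 4))
}

#' Specify a synthetic lipid-traffic simulation
#'
#' Declares the world a synthetic dataset is drawn from: the network, group
#' sizes, lipid panel, per-class log-normal abundance baselines, a detection
#' dropout probability, and the planted signal. By default every panel lipid
#' is present in both phenotypes at every compartment (background A-type),
#' so the plants are the only signal:
#' \describe{
#'   \item{\code{planted_switches}}{Each \code{list(lipid=, scope=,
#'     phenotype=)} makes the lipid present at the scope (a compartment id,
#'     or a length-2 axis) for that phenotype and absent there for the
#'     other, i.e. a B-type plant.}
#'   \item{\code{planted_ubiquitous}}{Each \code{list(lipid=, phenotype=)}
#'     makes the lipid present at every compartment for that phenotype and
#'     absent everywhere for the other (a U-type plant).}
#'   \item{\code{planted_effects}}{Each \code{list(unit=, compartment=,
#'     fold=)} multiplies the case-group abundance of a species (or every
#'     species of a class) by \code{fold} in that compartment.}
#'   \item{\code{absences}}{Each \code{list(unit=, compartment=,
#'     phenotype=)} (phenotype may be \code{"both"}) removes a species or a
#'     whole class from a compartment, e.g. triglycerides from brain.}
#' }
#'
#' @param network A \code{\link{traffic_network}} (default the bundled
#'   8-compartment serum-hub star).
#' @param phenotypes Two labels; the first is the reference group.
#' @param n_per_group Samples per (phenotype, compartment); default 5.
#' @param lipid_panel Character vector of species names.
#' @param class_baselines data.frame(head_group, log_mean, log_sd).
#' @param detection_dropout Probability in [0, 0.34) that a truly-present
#'   lipid yields signal 0 in a given sample (kept below 1 - 0.66 so plants
#'   survive the presence rule in expectation).
#' @param planted_switches,planted_ubiquitous,planted_effects,absences
#'   Lists as described above.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return A validated \code{simulation_design}.
#' @export
simulation_design <- function(network = default_network(),
                              phenotypes = c("control", "diabetic"),
                              n_per_group = 5L,
                              lipid_panel = default_lipid_panel(),
                              class_baselines = default_class_baselines(),
                              detection_dropout = 0,
                              planted_switches = list(),
                              planted_ubiquitous = list(),
                              planted_effects = list(),
                              absences = list(),
                              seed = 1L) {
  stopifnot(inherits(network, "traffic_network"))
  phenotypes <- as.character(phenotypes)
  if (length(phenotypes) != 2L || anyDuplicated(phenotypes))
    stop("exactly two distinct phenotype labels required", call. = FALSE)
  n_per_group <- as.integer(n_per_group)
  stopifnot(n_per_group >= 1L)
  if (detection_dropout < 0 || detection_dropout >= 0.34)
    stop("detection_dropout must lie in [0, 0.34) so planted presences ",
         "survive the 66% rule in expectation", call. = FALSE)
  panel <- build_lipid_panel(lipid_panel, warn_unknown_head = FALSE)
  classes <- unique(panel$head_group)

  check_scope <- function(scope) {
    scope <- as.character(scope)
    if (length(scope) == 1L) {
      if (!scope %in% network$compartments)
        stop("plant references unknown compartment: ", scope, call. = FALSE)
    } else if (length(scope) == 2L) {
      match_axis(network, scope)
    } else stop("a plant scope is a compartment or a 2-compartment axis",
                call. = FALSE)
    scope
  }
  check_lipid <- function(nm) {
    canon <- render_lipid_name(parse_lipid_name(nm, warn_unknown_head = FALSE))
    if (!canon %in% panel$name)
      stop("plant references lipid outside the panel: ", nm, call. = FALSE)
    canon
  }
  check_phen <- function(g) {
    if (!g %in% phenotypes)
      stop("plant references unknown phenotype: ", g, call. = FALSE)
    g
  }

  planted_switches <- lapply(planted_switches, function(p)
    list(lipid = check_lipid(p$lipid), scope = check_scope(p$scope),
         phenotype = check_phen(p$phenotype)))
  # Contradiction: one lipid B-planted for both phenotypes at one scope.
  if (length(planted_switches)) {
    keys <- vapply(planted_switches, function(p)
      paste(p$lipid, paste(sort(p$scope), collapse = "|"), sep = "@"), "")
    for (k in unique(keys)) {
      gs <- unique(vapply(planted_switches[keys == k], `[[`, "", "phenotype"))
      if (length(gs) > 1L)
        stop("inconsistent plants: ", sub("@.*", "", k),
             " planted B-type for both phenotypes at the same scope",
             call. = FALSE)
    }
  }
  planted_ubiquitous <- lapply(planted_ubiquitous, function(p)
    list(lipid = check_lipid(p$lipid), phenotype = check_phen(p$phenotype)))
  planted_effects <- lapply(planted_effects, function(p) {
    unit <- as.character(p$unit)
    if (!unit %in% classes) unit <- check_lipid(unit)
    if (!is.numeric(p$fold) || p$fold <= 0)
      stop("planted fold changes must be > 0", call. = FALSE)
    list(unit = unit, compartment = check_scope(p$compartment)[1],
         fold = as.numeric(p$fold))
  })
  absences <- lapply(absences, function(p) {
    unit <- as.character(p$unit)
    if (!unit %in% classes) unit <- check_lipid(unit)
    g <- as.character(p$phenotype)
    if (!g %in% c("both", phenotypes))
      stop("absence phenotype must be a group label or 'both'", call. = FALSE)
    list(unit = unit, compartment = check_scope(p$compartment)[1], phenotype = g)
  })

  design <- structure(list(network = network, phenotypes = phenotypes,
                           n_per_group = n_per_group, panel = panel,
                           class_baselines = class_baselines,
                           detection_dropout = detection_dropout,
                           planted_switches = planted_switches,
                           planted_ubiquitous = planted_ubiquitous,
                           planted_effects = planted_effects,
                           absences = absences,
                           seed = as.integer(seed)),
                      class = "simulation_design")
  # The designed presence pattern must realise every plant; building it
  # also catches plants that overwrite each other.
  design_presence(design, check = TRUE)
  design
}

# The noise-free presence pattern implied by a design: data.table
# (lipid, compartment, phenotype, present).
design_presence <- function(design, check = FALSE) {
  panel <- design$panel
  net <- design$network
  phen <- design$phenotypes
  pres <- CJ(lipid = panel$name, compartment = net$compartments,
             phenotype = phen, sorted = FALSE)
  pres[, present := TRUE]
  set_pres <- function(lipids, comps, groups, value) {
    pres[lipid %in% lipids & compartment %in% comps & phenotype %in% groups,
         present := value]
  }
  for (a in design$absences) {
    lipids <- if (a$unit %in% panel$head_group)
      panel$name[panel$head_group == a$unit] else a$unit
    groups <- if (a$phenotype == "both") phen else a$phenotype
    set_pres(lipids, a$compartment, groups, FALSE)
  }
  for (p in design$planted_ubiquitous) {
    other <- setdiff(phen, p$phenotype)
    set_pres(p$lipid, net$compartments, p$phenotype, TRUE)
    set_pres(p$lipid, net$compartments, other, FALSE)
  }
  for (p in design$planted_switches) {
    other <- setdiff(phen, p$phenotype)
    set_pres(p$lipid, p$scope, p$phenotype, TRUE)
    set_pres(p$lipid, p$scope, other, FALSE)
  }
  if (check) {
    for (p in design$planted_ubiquitous) {
      ok <- pres[lipid == p$lipid & phenotype == p$phenotype, all(present)]
      if (!ok)
        stop("inconsistent plants: ubiquitous plant for ", p$lipid,
             " (", p$phenotype, ") is overwritten elsewhere", call. = FALSE)
    }
    for (p in design$planted_switches) {
      other <- setdiff(phen, p$phenotype)
      ok <- pres[lipid == p$lipid & compartment %in% p$scope,
                 all(present[phenotype == p$phenotype]) &&
                 !any(present[phenotype == other])]
      if (!ok)
        stop("inconsistent plants: switch plant for ", p$lipid, " at ",
             paste(p$scope, collapse = "-"), " is overwritten", call. = FALSE)
    }
  }
  pres
}

# Ground truth derived from the design alone (no simulation): the designed
# presence map, its A/B/U classification at every scope, and the expected
# sign of every planted abundance effect.
ground_truth <- function(design) {
  pres <- design_presence(design)
  pm <- presence_map_from_logical(pres, design$network, design$panel,
                                  sort(design$phenotypes),
                                  n = design$n_per_group)
  jp <- jaccard_params(100L, seed = design$seed)
  sw <- run_switch(pm, design$network, jp)
  reference <- design$phenotypes[1]
  panel <- design$panel
  signs <- rbindlist(lapply(design$planted_effects, function(p)
    data.table(unit = p$unit, compartment = p$compartment, fold = p$fold,
               expected_sign = sign(log(p$fold)))))
  list(presence = pres,
       types = sw$types,
       ubiquitous = sw$ubiquitous,
       enfc_signs = if (length(design$planted_effects)) signs else
         data.table(unit = character(0), compartment = character(0),
                    fold = numeric(0), expected_sign = numeric(0)),
       reference = reference,
       design = design)
}

#' Simulate a synthetic lipidomics dataset
#'
#' Draws one dataset from a \code{\link{simulation_design}} together with
#' its machine-readable ground truth. For every (lipid, compartment,
#' phenotype) present in the design, each of the group's samples receives a
#' log-normal signal from its class baseline, multiplied by any planted fold
#' applying to the case group, then zeroed with probability
#' \code{detection_dropout}. Designed-absent combinations emit no record.
#' Identical seeds give identical datasets.
#'
#' @param design A \code{\link{simulation_design}}.
#' @return List with \code{table} (an \code{\link{abundance_table}}) and
#'   \code{truth} (designed presence, expected A/B/U classification per
#'   scope, expected ENFC signs, design echo).
#' @export
simulate_lta <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  truth <- ground_truth(design)
  panel <- design$panel
  net <- design$network
  phen <- design$phenotypes
  reference <- phen[1]
  base <- design$class_baselines
  fallback <- c(log_mean = 5, log_sd = 0.3)

  pres <- truth$presence[truth$presence$present == TRUE, ]
  # Fixed iteration order so the RNG stream, and hence the dataset, is
  # reproducible byte-for-byte.
  pres <- pres[order(lipid_order(lipid))]
  pres[, compartment := factor(compartment, levels = net$compartments)]
  pres[, phenotype := factor(phenotype, levels = phen)]
  setorderv(pres, c("compartment", "phenotype"))

  effects <- design$planted_effects
  fold_for <- function(lip, head, comp) {
    f <- 1
    for (e in effects)
      if (e$compartment == comp && (e$unit == lip || e$unit == head))
        f <- f * e$fold
    f
  }

  n <- design$n_per_group
  d <- design$detection_dropout
  rows <- vector("list", nrow(pres))
  with_seed(design$seed, {
    for (i in seq_len(nrow(pres))) {
      lip <- pres$lipid[i]
      comp <- as.character(pres$compartment[i])
      g <- as.character(pres$phenotype[i])
      head <- panel$head_group[match(lip, panel$name)]
      bi <- match(head, base$head_group)
      mlog <- if (is.na(bi)) fallback["log_mean"] else base$log_mean[bi]
      slog <- if (is.na(bi)) fallback["log_sd"] else base$log_sd[bi]
      fold <- if (g == reference) 1 else fold_for(lip, head, comp)
      sig <- rlnorm(n, meanlog = mlog + log(fold), sdlog = slog)
      if (d > 0) sig[runif(n) < d] <- 0
      rows[[i]] <- data.table(sample_id = sprintf("%s_%02d", g, seq_len(n)),
                              phenotype = g, compartment = comp,
                              lipid = lip, signal = sig)
    }
  })
  records <- rbindlist(rows)
  tbl <- abundance_table(records, net, warn_unknown_head = FALSE)
  list(table = tbl, truth = truth)
}

#' The bundled qualitative traffic fixture
#'
#' A simulation design encoding, as plants, the qualitative multi-tissue
#' findings this analysis is built to recover in a control-vs-diabetic
#' mouse design: control-only saturated DNL-marker TGs (TG(44:0), TG(46:0))
#' on the liver-serum axis against diabetic-only high double-bond PUFA-TGs
#' (TG(52:7), TG(58:11), TG(60:10), TG(60:11), TG(60:12)) on the same axis;
#' a PI swap on the serum-brain axis (control-only PI(36:2), PI(36:3) vs
#' diabetic-only PI(36:1), PI(38:6)); PC(32:1), PC(32:2), PC(34:4),
#' PC(36:6) and PE(40:7) ubiquitous in the control network only; PI(38:6)
#' more abundant in the diabetic liver and less abundant elsewhere; DNL
#' markers depleted and background PUFA-TGs enriched in the diabetic liver.
#' Triglycerides are absent from brain in both groups (so no TG is
#' ubiquitous), reflecting the low TG content of CNS tissue.
#'
#' @param n_per_group Samples per group per compartment (default 5).
#' @param detection_dropout Default 0 (noise-free presence pattern).
#' @param seed Integer seed.
#' @return A \code{\link{simulation_design}}.
#' @export
paper_fixture <- function(n_per_group = 5L, detection_dropout = 0, seed = 1L) {
  liver_serum <- c("liver", "serum")
  serum_brain <- c("serum", "brain")
  sw <- c(
    lapply(c("TG(44:0)", "TG(46:0)"), function(l)
      list(lipid = l, scope = liver_serum, phenotype = "control")),
    lapply(c("TG(52:7)", "TG(58:11)", "TG(60:10)", "TG(60:11)", "TG(60:12)"),
           function(l) list(lipid = l, scope = liver_serum, phenotype = "diabetic")),
    lapply(c("PI(36:2)", "PI(36:3)"), function(l)
      list(lipid = l, scope = serum_brain, phenotype = "control")),
    lapply(c("PI(36:1)", "PI(38:6)"), function(l)
      list(lipid = l, scope = serum_brain, phenotype = "diabetic"))
  )
  ub <- lapply(c("PC(32:1)", "PC(32:2)", "PC(34:4)", "PC(36:6)", "PE(40:7)"),
               function(l) list(lipid = l, phenotype = "control"))
  periphery <- c("spleen", "heart atria", "heart ventricles",
                 "renal medulla", "renal cortex")
  eff <- c(
    list(list(unit = "PI(38:6)", compartment = "liver", fold = 2)),
    lapply(periphery, function(cc)
      list(unit = "PI(38:6)", compartment = cc, fold = 0.5)),
    lapply(c("TG(48:0)", "TG(48:1)", "TG(50:0)", "TG(50:1)"), function(l)
      list(unit = l, compartment = "liver", fold = 0.5)),
    unlist(lapply(c("TG(54:7)", "TG(56:7)"), function(l) list(
      list(unit = l, compartment = "liver", fold = 2),
      list(unit = l, compartment = "serum", fold = 2),
      list(unit = l, compartment = "spleen", fold = 0.5))), recursive = FALSE)
  )
  abs_tg_brain <- list(list(unit = "TG", compartment = "brain",
                            phenotype = "both"))
  simulation_design(network = default_network(),
                    phenotypes = c("control", "diabetic"),
                    n_per_group = n_per_group,
                    detection_dropout = detection_dropout,
                    planted_switches = sw,
                    planted_ubiquitous = ub,
                    planted_effects = eff,
                    absences = abs_tg_brain,
                    seed = seed)
}
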