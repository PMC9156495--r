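#' Configuration for a full traffic-analysis run
#'
#' @param data Path to the abundance table (delimited text).
#' @param network Path to a network config file, or a
#'   \code{\link{traffic_network}}; \code{NULL} selects the bundled default.
#' @param out Output directory (created if needed).
#' @param reference Reference phenotype label (ENFC sign and B-type
#'   attribution are reported relative to it).
#' @param threshold_percent Presence threshold, default 66.
#' @param B_permutations Permutations per scope for the Jaccard test.
#' @param seed Integer seed; mandatory whenever permutation tests run.
#' @param alternative Jaccard test alternative, default \code{"two_sided"}.
#' @param policy A \code{\link{tagging_policy}}.
#' @param run_switch,run_abundance,run_panels Stage toggles.
#' @return A validated \code{run_config}.
#' @export
run_config <- function(data, network = NULL, out, reference,
                       threshold_percent = 66L, B_permutations = 10000L,
                       seed = NULL, alternative = "two_sided",
                       policy = tagging_policy(),
                       run_switch = TRUE, run_abundance = TRUE,
                       run_panels = TRUE) {
  if (!file.exists(data))
    stop("data file not found: ", data, call. = FALSE)
  if (is.character(network) && !file.exists(network))
    stop("network file not found: ", network, call. = FALSE)
  if (run_switch && is.null(seed))
    stop("an explicit --seed is required when permutation tests are enabled",
         call. = FALSE)
  structure(list(data = data, network = network, out = out,
                 reference = as.character(reference),
                 threshold_percent = as.integer(threshold_percent),
                 B_permutations = as.integer(B_permutations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 alternative = alternative, policy = policy,
                 run_switch = isTRUE(run_switch),
                 run_abundance = isTRUE(run_abundance),
                 run_panels = isTRUE(run_panels)),
            class = "run_config")
}

#' Run the full lipid traffic analysis
#'
#' Executes read -> presence -> switch analysis (with Jaccard tests) ->
#' abundance analysis (class ENFC plus DNL/PUFA subclass panels), writing
#' all result tables, a structured run summary and a per-stage log to the
#' output directory. Output ordering is deterministic (scopes in network
#' declaration order, lipids by head group then carbons then double bonds),
#' so two runs with identical config and inputs produce byte-identical
#' bundles.
#'
#' @param cfg A \code{\link{run_config}}.
#' @param quiet Suppress per-stage log messages.
#' @return Invisibly, a list with the in-memory results and the paths of
#'   every file written.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (!quiet) message("[lta] ", sprintf(...))
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)

  net <- if (is.null(cfg$network)) default_network()
         else if (inherits(cfg$network, "traffic_network")) cfg$network
         else read_network(cfg$network)
  say("network: %d compartments, %d axes",
      length(net$compartments), nrow(net$axes))

  tbl <- read_abundance_table(cfg$data, net, policy = cfg$policy,
                              warn_unknown_head = FALSE)
  panel <- at_panel(tbl)
  phen <- at_phenotypes(tbl)
  if (!cfg$reference %in% phen)
    stop("reference phenotype '", cfg$reference,
         "' not present in data (labels: ", paste(phen, collapse = ", "), ")",
         call. = FALSE)
  say("read %d records, %d lipid variables, phenotypes: %s",
      nrow(tbl), nrow(panel), paste(phen, collapse = " vs "))

  paths <- character(0)
  results <- list(network = net, table = tbl)
  wr <- function(dt, name) {
    p <- file.path(cfg$out, name)
    fwrite(dt, p, sep = "\t")
    paths[[name]] <<- p
    p
  }

  pm <- call_presence(tbl, cfg$threshold_percent)
  results$presence <- pm
  wr(as.data.table(pm), "presence.tsv")
  say("presence called at >=%d%%: %d of %d (lipid, compartment, phenotype) calls positive",
      cfg$threshold_percent, sum(pm$present), nrow(pm))

  if (cfg$run_switch) {
    jp <- jaccard_params(cfg$B_permutations, seed = cfg$seed,
                         alternative = cfg$alternative)
    sw <- run_switch(pm, net, jp)
    results$switch <- sw
    types_out <- copy(sw$types)
    types_out[, tags := panel$tags[match(lipid, panel$name)]]
    wr(types_out, "switch_types.tsv")
    ub_out <- copy(sw$ubiquitous)
    if (nrow(ub_out)) ub_out[, tags := panel$tags[match(lipid, panel$name)]]
    wr(ub_out, "switch_ubiquitous.tsv")
    wr(sw$jaccard, "jaccard.tsv")
    say("switch analysis: %d A-type, %d B-type calls over %d scopes; %d U-type attributions",
        sum(sw$types$type == "A"), sum(sw$types$type == "B"),
        length(net$compartments) + nrow(net$axes), nrow(sw$ubiquitous))
  }

  if (cfg$run_abundance) {
    ce <- class_enfc(tbl, cfg$reference)
    results$class_enfc <- ce
    wr(ce, "enfc_class.tsv")
    say("class ENFC: %d records (%d undefined)", nrow(ce), sum(ce$undefined))
  }

  if (cfg$run_panels) {
    for (tag in c("DNL_MARKER", "PUFA")) {
      pnl <- tryCatch(subclass_panel(tbl, tag, cfg$reference),
                      error = function(e) NULL)
      if (is.null(pnl)) {
        say("panel %s: no species selected, skipped", tag)
        next
      }
      results[[paste0("panel_", tolower(tag))]] <- pnl
      wr(pnl, sprintf("enfc_panel_%s.tsv", tolower(tag)))
      say("panel %s: %d records", tag, nrow(pnl))
    }
  }

  summary <- list(
    software = "lipidtraffic",
    version = as.character(packageVersion("lipidtraffic")),
    # file basenames, not full paths, so bundles from identical inputs are
    # byte-identical regardless of where the inputs live
    config = list(data = basename(cfg$data),
                  network = if (is.character(cfg$network)) basename(cfg$network) else "default",
                  reference = cfg$reference,
                  threshold_percent = cfg$threshold_percent,
                  B_permutations = cfg$B_permutations,
                  seed = cfg$seed,
                  alternative = cfg$alternative),
    counts = list(records = nrow(tbl), lipids = nrow(panel),
                  compartments = length(net$compartments),
                  axes = nrow(net$axes))
  )
  sp <- file.path(cfg$out, "run_summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  paths[["run_summary.json"]] <- sp
  results$paths <- paths
  say("wrote %d files to %s", length(paths), cfg$out)
  invisible(results)
}

#' Simulate a dataset to disk
#'
#' Writes a synthetic abundance table and its ground truth, ready for
#' \code{\link{run_pipeline}} or external tools. The design is either the
#' bundled \code{"paper-fixture"} or a JSON design file (fields mirroring
#' \code{\link{simulation_design}} arguments; plant lists as arrays of
#' objects).
#'
#' @param design \code{"paper-fixture"} or a path to a JSON design file.
#' @param out Output directory.
#' @param seed Integer seed (overrides the design's own seed).
#' @param quiet Suppress the summary line.
#' @return Invisibly, list with \code{table}, \code{truth} and file paths.
#' @export
simulate_command <- function(design, out, seed = NULL, quiet = FALSE) {
  dsg <- if (identical(design, "paper-fixture")) {
    paper_fixture(seed = if (is.null(seed)) 1L else as.integer(seed))
  } else {
    read_design_json(design, seed = seed)
  }
  sim <- simulate_lta(dsg)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dp <- file.path(out, "abundance.tsv")
  write_abundance_table(sim$table, dp)
  np <- file.path(out, "network.txt")
  write_network(dsg$network, np)
  tp <- file.path(out, "ground_truth.json")
  jsonlite::write_json(
    list(reference = sim$truth$reference,
         phenotypes = dsg$phenotypes,
         n_per_group = dsg$n_per_group,
         seed = dsg$seed,
         presence = sim$truth$presence,
         types = sim$truth$types,
         ubiquitous = sim$truth$ubiquitous,
         enfc_signs = sim$truth$enfc_signs),
    tp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!quiet)
    message(sprintf("[lta] simulated %d lipids x %d compartments x 2 phenotypes (n=%d per group) -> %s",
                    nrow(dsg$panel), length(dsg$network$compartments),
                    dsg$n_per_group, out))
  invisible(list(table = sim$table, truth = sim$truth,
                 paths = c(abundance = dp, network = np, truth = tp)))
}

# Minimal JSON design reader: scalar fields plus plant arrays.
read_design_json <- function(path, seed = NULL) {
  if (!file.exists(path))
    stop("design file not found: ", path, call. = FALSE)
  `%||%` <- function(a, b) if (is.null(a)) b else a
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  net <- if (!is.null(js$network_file)) read_network(js$network_file)
         else if (!is.null(js$network))
           traffic_network(unlist(js$network$compartments),
                           lapply(js$network$axes, unlist))
         else default_network()
  simulation_design(
    network = net,
    phenotypes = if (!is.null(js$phenotypes)) unlist(js$phenotypes)
                 else c("control", "diabetic"),
    n_per_group = js$n_per_group %||% 5L,
    lipid_panel = if (!is.null(js$lipid_panel)) unlist(js$lipid_panel)
                  else default_lipid_panel(),
    detection_dropout = js$detection_dropout %||% 0,
    planted_switches = lapply(js$planted_switches %||% list(), function(p)
      list(lipid = p$lipid, scope = unlist(p$scope), phenotype = p$phenotype)),
    planted_ubiquitous = lapply(js$planted_ubiquitous %||% list(), function(p)
      list(lipid = p$lipid, phenotype = p$phenotype)),
    planted_effects = lapply(js$planted_effects %||% list(), function(p)
      list(unit = p$unit, compartment = p$compartment, fold = p$fold)),
    absences = lapply(js$absences %||% list(), function(p)
      list(unit = p$unit, compartment = p$compartment, phenotype = p$phenotype)),
    seed = if (!is.null(seed)) as.integer(seed) else (js$seed %||% 1L)
  )
}
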