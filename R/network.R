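#' Construct a traffic network
#'
#' A traffic network names the sampled compartments (tissues and fluids) and
#' the axes (edges) connecting them. Lipids are traced over this graph: a
#' lipid sits on an axis for a phenotype when it is present at both endpoint
#' compartments.
#'
#' @param compartments Character vector of unique, case-sensitive compartment
#'   ids, in the order results should be reported.
#' @param axes List of length-2 character vectors (unordered compartment
#'   pairs), or a 2-column character matrix. May be empty only for a
#'   single-compartment network.
#' @return An object of class \code{traffic_network} with elements
#'   \code{compartments} (character) and \code{axes} (2-column character
#'   matrix, one row per axis in declaration order).
#' @details The network must be connected, free of self-loops, and every axis
#'   endpoint must be a declared compartment.
#' @examples
#' traffic_network(c("serum", "liver"), list(c("serum", "liver")))
#' @export
traffic_network <- function(compartments, axes = list()) {
  compartments <- as.character(compartments)
  if (length(compartments) < 1L)
    stop("network needs at least one compartment", call. = FALSE)
  if (anyDuplicated(compartments))
    stop("compartment ids must be unique (case-sensitive): duplicated ",
         paste(unique(compartments[duplicated(compartments)]), collapse = ", "),
         call. = FALSE)
  if (is.matrix(axes)) axes <- lapply(seq_len(nrow(axes)), function(i) axes[i, ])
  amat <- if (length(axes) == 0L) {
    matrix(character(0), ncol = 2L)
  } else {
    do.call(rbind, lapply(axes, function(a) {
      a <- as.character(a)
      if (length(a) != 2L)
        stop("each axis must name exactly two compartments", call. = FALSE)
      a
    }))
  }
  unknown <- setdiff(as.vector(amat), compartments)
  if (length(unknown))
    stop("axis endpoint(s) not declared as compartments: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(amat) && any(amat[, 1] == amat[, 2]))
    stop("self-loop axes are not allowed: ",
         paste(unique(amat[amat[, 1] == amat[, 2], 1]), collapse = ", "),
         call. = FALSE)
  keys <- apply(amat, 1, function(a) paste(sort(a), collapse = "\r"))
  if (anyDuplicated(keys))
    stop("duplicate axes declared", call. = FALSE)
  net <- structure(list(compartments = compartments, axes = amat),
                   class = "traffic_network")
  if (!network_is_connected(net))
    stop("network is not connected: every compartment must be reachable ",
         "from every other", call. = FALSE)
  net
}

# Breadth-first search connectivity over the undirected axis set.
network_is_connected <- function(net) {
  comps <- net$compartments
  if (length(comps) == 1L) return(TRUE)
  adj <- setNames(vector("list", length(comps)), comps)
  for (i in seq_len(nrow(net$axes))) {
    a <- net$axes[i, 1]; b <- net$axes[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(logical(length(comps)), comps)
  queue <- comps[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nxt <- adj[[cur]][!seen[adj[[cur]]]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

#' @export
print.traffic_network <- function(x, ...) {
  cat(sprintf("<traffic_network> %d compartments, %d axes\n",
              length(x$compartments), nrow(x$axes)))
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  if (nrow(x$axes))
    cat("  axes:", paste(apply(x$axes, 1, paste, collapse = "-"),
                         collapse = ", "), "\n")
  invisible(x)
}

axis_label <- function(axis) paste(axis, collapse = "-")

# Match an axis (in either endpoint order) against the network; returns the
# row index or throws.
match_axis <- function(net, axis) {
  axis <- as.character(axis)
  if (length(axis) != 2L)
    stop("an axis is a pair of compartments", call. = FALSE)
  key <- paste(sort(axis), collapse = "\r")
  keys <- apply(net$axes, 1, function(a) paste(sort(a), collapse = "\r"))
  i <- match(key, keys)
  if (is.na(i))
    stop("unknown axis: ", axis_label(axis), call. = FALSE)
  i
}

#' Read a traffic network from a configuration file
#'
#' The configuration is a small indented key/list dialect with two keys,
#' \code{compartments:} (a list of ids) and \code{axes:} (a list of 2-item
#' lists). List items start with \code{"- "}; an axis item is written
#' \code{- [a, b]} (or \code{- a, b}). Lines starting with \code{#} are
#' comments. A default 8-compartment file is bundled; see
#' \code{\link{default_network}}.
#'
#' @param path Path to the configuration file.
#' @return A validated \code{\link{traffic_network}}.
#' @export
read_network <- function(path) {
  if (!file.exists(path))
    stop("network config not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  current <- NULL
  compartments <- character(0)
  axes <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) next
    trimmed <- trimws(line)
    if (grepl("^(compartments|axes):\\s*$", trimmed)) {
      current <- sub(":\\s*$", "", trimmed)
    } else if (grepl("^- ", trimmed)) {
      if (is.null(current))
        stop(sprintf("network config line %d: list item outside a section", i),
             call. = FALSE)
      item <- trimws(sub("^- ", "", trimmed))
      if (current == "compartments") {
        compartments <- c(compartments, item)
      } else {
        item <- gsub("^\\[|\\]$", "", item)
        pair <- trimws(strsplit(item, ",", fixed = TRUE)[[1]])
        if (length(pair) != 2L)
          stop(sprintf("network config line %d: an axis needs two compartments", i),
               call. = FALSE)
        axes <- c(axes, list(pair))
      }
    } else {
      stop(sprintf("network config line %d: cannot parse '%s'", i, trimmed),
           call. = FALSE)
    }
  }
  traffic_network(compartments, axes)
}

#' The default multi-tissue traffic network
#'
#' Eight compartments with serum as the hub: serum connected by one axis to
#' each of liver, brain, heart atria, heart ventricles, spleen, renal medulla
#' and renal cortex (7 axes). This star topology is a documented assumption
#' reflecting that the exchange of circulating lipids between solid tissues
#' passes through serum; it is fully overridable via \code{\link{read_network}}.
#'
#' @return A \code{\link{traffic_network}} with 8 compartments and 7 axes.
#' @export
default_network <- function() {
  read_network(system.file("extdata", "network_default.txt",
                           package = "lipidtraffic", mustWork = TRUE))
}

#' Write a traffic network configuration file
#'
#' @param net A \code{\link{traffic_network}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "traffic_network"))
  lines <- c("compartments:",
             paste0("  - ", net$compartments),
             "axes:",
             if (nrow(net$axes))
               paste0("  - [", net$axes[, 1], ", ", net$axes[, 2], "]"))
  writeLines(lines, path)
  invisible(path)
}
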