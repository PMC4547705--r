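#' Feedforward dissemination network topology
#'
#' Builds the compartment graph on which the branching process lives: a
#' single source node (the draining lymph nodes, where primed cells
#' proliferate and from which they egress), a serial chain of transfer
#' stages (lymphatic/blood vessel legs of the journey), and a set of sink
#' organs (spleen and distal lymph nodes) that receive migrating cells and
#' never feed back into the network.
#'
#' The number of transfer stages equals the transit time expressed in model
#' steps, `round(transit_hours / dt_hours)`: each stage is one step-long leg
#' of the source-to-sink journey.  The first leg is traversed during the
#' same step in which the cell leaves the source (egress and the first leg
#' share one fate draw), so a cell that migrates during step `n -> n+1`
#' occupies stage 2 at `n+1` and enters a sink exactly `n_transfer_stages`
#' steps after the migration decision.  With the defaults (12 h transit,
#' 4 h step) cells leaving the source at the first step reach the sinks at
#' step 3, i.e. 84 h post-immunization when step 0 is 72 h.  Stage 1 is
#' kept in the state space so that stages map one-to-one onto transit legs
#' and user-supplied initial conditions can place cells anywhere along the
#' route.
#'
#' @param transit_hours source-to-sink transit time in hours (default 12).
#' @param dt_hours duration of one model step in hours (default 4).
#' @param n_transfer_stages override the stage count directly; when given,
#'   `transit_hours` is ignored.
#' @param source label of the source compartment.
#' @param sinks named character vector mapping sink compartment labels to
#'   the keys of the splitting-probability vector `rho`
#'   (default `c(SPL = "spl", ILN = "il", MLN = "mes")`).  May be empty for
#'   a source-only toy network (migration must then be zero).
#' @return an object of class `mgw_topology`.
#' @examples
#' topo <- network_topology()            # 12 h / 4 h -> 3 transfer stages
#' topo$transfer_stages
#' @export
network_topology <- function(transit_hours = 12, dt_hours = 4,
                             n_transfer_stages = NULL,
                             source = "DR",
                             sinks = c(SPL = "spl", ILN = "il", MLN = "mes")) {
  if (is.null(n_transfer_stages)) {
    if (!is.numeric(transit_hours) || !is.numeric(dt_hours) || dt_hours <= 0)
      stop("'transit_hours' and 'dt_hours' must be positive numbers")
    n_transfer_stages <- as.integer(round(transit_hours / dt_hours))
  }
  n_transfer_stages <- as.integer(n_transfer_stages)
  if (is.na(n_transfer_stages) || n_transfer_stages < 0L)
    stop("number of transfer stages must be a non-negative integer")
  if (length(source) != 1L || !nzchar(source))
    stop("'source' must be a single non-empty label")
  if (length(sinks) > 0L && is.null(names(sinks)))
    stop("'sinks' must be a named character vector (label -> rho key)")
  if (length(sinks) == 0L && n_transfer_stages > 0L)
    stop("a network with transfer stages needs at least one sink")
  stages <- if (n_transfer_stages > 0L) paste0("TR", seq_len(n_transfer_stages)) else character(0)
  labs <- c(source, stages, names(sinks))
  if (anyDuplicated(labs)) stop("compartment labels must be unique")
  structure(
    list(source = source,
         transfer_stages = stages,
         sinks = names(sinks),
         rho_keys = sinks,
         transit_hours = n_transfer_stages * dt_hours,
         dt_hours = dt_hours),
    class = "mgw_topology")
}

#' @export
print.mgw_topology <- function(x, ...) {
  cat("Feedforward dissemination network\n")
  cat("  source :", x$source, "\n")
  cat("  transit:", length(x$transfer_stages), "stages (",
      x$transit_hours, "h at", x$dt_hours, "h/step )\n")
  cat("  sinks  :", if (length(x$sinks)) paste(x$sinks, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Compartment labels of a topology, in state-space order
#' @param topology an `mgw_topology`.
#' @return character vector: source, transfer stages, sinks.
#' @export
compartments <- function(topology) {
  stopifnot(inherits(topology, "mgw_topology"))
  c(topology$source, topology$transfer_stages, topology$sinks)
}

#' Type space of the multi-type process
#'
#' Enumerates the types (compartment, generation) of the branching process
#' and fixes their vector/matrix indexing.  Compartments appear in the
#' order source, transfer stages, sinks; generations 0..p ascend within
#' each compartment.  The ordering is deterministic, so two calls with the
#' same inputs give identical index maps.
#'
#' @param topology an `mgw_topology`.
#' @param p maximum trackable generation (integer >= 2); cells beyond `p`
#'   divisions are pooled at generation `p` (dye-diluted beyond resolution).
#' @return an object of class `mgw_type_space`: a data.frame with columns
#'   `index`, `compartment`, `generation`, carrying an index-lookup
#'   attribute.
#' @examples
#' ts <- build_type_space(network_topology(), p = 7)
#' nrow(ts)   # 7 compartments x 8 generations = 56 types
#' @export
build_type_space <- function(topology, p) {
  stopifnot(inherits(topology, "mgw_topology"))
  p <- as.integer(p)
  if (is.na(p) || p < 2L) stop("'p' must be an integer >= 2")
  comps <- compartments(topology)
  if (length(comps) == 0L) stop("topology has no compartments")
  gens <- 0:p
  df <- data.frame(
    index = seq_len(length(comps) * length(gens)),
    compartment = rep(comps, each = length(gens)),
    generation = rep(gens, times = length(comps)),
    stringsAsFactors = FALSE)
  lookup <- matrix(df$index, nrow = length(gens), ncol = length(comps),
                   dimnames = list(gens, comps))
  attr(df, "lookup") <- lookup
  attr(df, "p") <- p
  attr(df, "labels") <- paste0(df$compartment, ":", df$generation)
  class(df) <- c("mgw_type_space", "data.frame")
  df
}

#' Index of a (compartment, generation) type
#' @param type_space an `mgw_type_space`.
#' @param compartment compartment label(s).
#' @param generation generation number(s), 0-based.
#' @return integer index/indices into the type space.
#' @export
type_index <- function(type_space, compartment, generation) {
  lookup <- attr(type_space, "lookup")
  if (is.null(lookup)) stop("not a type space")
  n <- max(length(compartment), length(generation))
  compartment <- rep_len(compartment, n)
  generation <- rep_len(generation, n)
  bad <- !(compartment %in% colnames(lookup)) | generation < 0 |
    generation > attr(type_space, "p")
  if (any(bad))
    stop("unknown type(s): ",
         paste0(compartment[bad], ":", generation[bad], collapse = ", "))
  lookup[cbind(generation + 1L, match(compartment, colnames(lookup)))]
}
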