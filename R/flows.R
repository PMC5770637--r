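# Mass-balance inference of annual between-compartment tracer flows.
#
# The recovery time series give, per compartment, the change in % of applied
# tracer over an interval. Given a directed flow topology with a resolution
# order (each node, visited in order, has exactly one unknown incident edge),
# the flows are solved bottom-up from the node balances
#   inflows - outflows = delta,
# leaving one residual edge (moss -> loss) that absorbs whatever the measured
# compartments cannot account for: the unattributed (gaseous) loss.

#' Default tracer flow topology
#'
#' Nodes are aggregated pools: `plants` (all dwarf-shrub fractions plus
#' current-year litter), `moss`, the `O`/`A`/`B` soil horizons, and the
#' absorbing nodes `leachate` and `loss`. Edges follow the downward cascade
#' moss -> O -> A -> B -> leachate, plant uptake from the O-horizon with
#' litter returned to it, and the residual edge moss -> loss interpreted as
#' gaseous loss. Upward transport (bioturbation) appears as a negative
#' O -> A flow rather than as an extra cycle. The resolution order solves
#' B, A, plants, O, then moss; the edges `plants -> O` (litter return) and
#' `B -> leachate` are fixed inputs.
#'
#' @return A list of class `flow_topology` with elements `edges` (tibble
#'   `from`, `to`, `type` in `known`/`unknown`/`residual`), `order` (node
#'   resolution order), and `node_map` (compartment name -> node).
#' @export
flow_topology <- function() {
  edges <- tibble::tribble(
    ~from,    ~to,        ~type,
    "moss",   "O",        "unknown",    # release to organic layer
    "moss",   "loss",     "residual",   # unattributed (gaseous) loss
    "O",      "A",        "unknown",    # downward soil transport
    "A",      "B",        "unknown",
    "B",      "leachate", "known",      # measured leachate export
    "O",      "plants",   "unknown",    # plant uptake
    "plants", "O",        "known"       # litter return
  )
  node_map <- c(
    current_year_shoots = "plants", shoots_1_2yr = "plants",
    calluna_old = "plants", calluna_roots = "plants",
    litter_current = "plants", moss = "moss",
    O_horizon = "O", A_horizon = "A", B_horizon = "B",
    leachate = "leachate")
  structure(list(edges = edges,
                 order = c("B", "A", "plants", "O", "moss"),
                 node_map = node_map),
            class = "flow_topology")
}

#' Change in recovery per compartment over an interval
#'
#' @param table Recovery table (columns `compartment`, `year`,
#'   `recovery_mean`, % of applied tracer).
#' @param year_from,year_to Interval endpoints; both must be present for a
#'   compartment, otherwise it is excluded with a message.
#' @param annualize Divide by the interval length in years.
#' @return A tibble `compartment, delta` in percentage points of the applied
#'   tracer (per year if `annualize`).
#' @export
compartment_deltas <- function(table, year_from, year_to, annualize = FALSE) {
  stopifnot(all(c("compartment", "year", "recovery_mean") %in% names(table)),
            year_to >= year_from)
  wide <- table |>
    dplyr::filter(.data$year %in% c(year_from, year_to)) |>
    dplyr::select("compartment", "year", "recovery_mean") |>
    tidyr::pivot_wider(names_from = "year", values_from = "recovery_mean",
                       names_prefix = "y")
  cols <- paste0("y", c(year_from, year_to))
  for (cl in setdiff(cols, names(wide))) wide[[cl]] <- NA_real_
  excluded <- wide$compartment[is.na(wide[[cols[1]]]) | is.na(wide[[cols[2]]])]
  if (length(excluded)) {
    message("excluded from deltas (missing endpoint year): ",
            paste(excluded, collapse = ", "))
  }
  span <- if (annualize && year_to > year_from) year_to - year_from else 1
  wide |>
    dplyr::filter(!.data$compartment %in% excluded) |>
    dplyr::mutate(delta = (.data[[cols[2]]] - .data[[cols[1]]]) / span) |>
    dplyr::select("compartment", "delta")
}

#' Infer between-compartment tracer flows from recovery changes
#'
#' Solves the flow topology in one bottom-up pass: at each node of the
#' resolution order the single unknown incident edge is set so that
#' inflows minus outflows equal the node's recovery change. The residual edge
#' absorbs the remaining moss imbalance and is reported as the unattributed
#' loss. All quantities are in percentage points of the applied tracer over
#' the interval. A negative residual (apparent creation of tracer) is
#' reported with a warning, not clamped.
#'
#' @param deltas Per-compartment recovery changes from [compartment_deltas()]
#'   (or any tibble `compartment, delta`; compartments are aggregated to
#'   topology nodes via the topology's `node_map`).
#' @param topology A [flow_topology()].
#' @param litter_flux Known plant-to-O litter tracer flux (% applied) over
#'   the interval.
#' @param leachate_flux Known leachate tracer export (% applied) over the
#'   interval.
#' @return A tibble of class `flow_ledger`: columns `from, to, type, flow`
#'   (% of applied tracer), with attributes `deltas` (node deltas used),
#'   `residual`, and `interval`.
#' @examples
#' d <- tibble::tibble(compartment = c("moss", "O_horizon"),
#'                     delta = c(-10, 4))
#' infer_flows(d)
#' @export
infer_flows <- function(deltas, topology = flow_topology(),
                        litter_flux = 0, leachate_flux = 0) {
  stopifnot(inherits(topology, "flow_topology"),
            all(c("compartment", "delta") %in% names(deltas)))
  check_number(litter_flux, what = "litter_flux")
  check_number(leachate_flux, what = "leachate_flux")

  node_map <- topology$node_map
  unknown_node <- setdiff(unique(as.character(deltas$compartment)),
                          names(node_map))
  if (length(unknown_node)) {
    stop("compartment(s) not mapped to a topology node: ",
         paste(unknown_node, collapse = ", "), call. = FALSE)
  }
  node_delta <- deltas |>
    dplyr::mutate(node = unname(node_map[as.character(.data$compartment)])) |>
    dplyr::summarise(delta = sum(.data$delta), .by = "node")
  delta_of <- function(n) {
    i <- match(n, node_delta$node)
    if (is.na(i)) 0 else node_delta$delta[i]
  }

  edges <- topology$edges
  edges$flow <- NA_real_
  known <- edges$type == "known"
  edges$flow[known & edges$from == "plants" & edges$to == "O"] <- litter_flux
  edges$flow[known & edges$to == "leachate"] <- leachate_flux
  edges$flow[known & is.na(edges$flow)] <- 0

  for (node in topology$order) {
    inc <- which(edges$from == node | edges$to == node)
    open <- inc[is.na(edges$flow[inc])]
    if (length(open) != 1) {
      stop("topology not solvable in one pass: node '", node, "' has ",
           length(open), " unknown incident edges", call. = FALSE)
    }
    # balance: sum(in) - sum(out) = delta  ->  solve the open edge
    bal <- sum(edges$flow[inc][edges$to[inc] == node], na.rm = TRUE) -
      sum(edges$flow[inc][edges$from[inc] == node], na.rm = TRUE)
    need <- delta_of(node) - bal
    # outgoing open edge: flow = -need; incoming: flow = need
    edges$flow[open] <- if (edges$from[open] == node) -need else need
  }

  residual <- edges$flow[edges$type == "residual"]
  if (length(residual) == 1 && residual < 0) {
    warning("negative residual loss (", round(residual, 3),
            " % applied): apparent tracer creation, likely measurement noise",
            call. = FALSE)
  }

  out <- tibble::as_tibble(edges)
  class(out) <- c("flow_ledger", class(out))
  attr(out, "deltas") <- node_delta
  attr(out, "residual") <- residual
  attr(out, "litter_flux") <- litter_flux
  attr(out, "leachate_flux") <- leachate_flux
  validate_ledger_closure(out)
  out
}

# every interior node must close: inflow - outflow = delta (<= 1e-9)
validate_ledger_closure <- function(ledger, tol = 1e-9) {
  node_delta <- attr(ledger, "deltas")
  nodes <- unique(c(ledger$from, ledger$to))
  interior <- setdiff(nodes, c("loss", "leachate", "atmosphere"))
  for (node in interior) {
    bal <- sum(ledger$flow[ledger$to == node]) -
      sum(ledger$flow[ledger$from == node])
    d <- node_delta$delta[match(node, node_delta$node)]
    if (is.na(d)) d <- 0
    if (abs(bal - d) > tol) {
      stop("ledger fails to close at node '", node, "': balance ", bal,
           " vs delta ", d, call. = FALSE)
    }
  }
  invisible(ledger)
}

#' @export
print.flow_ledger <- function(x, ...) {
  cat("<flow_ledger> flows in % of applied tracer\n")
  NextMethod()
  cat(sprintf("residual (unattributed loss): %.3f %% applied\n",
              attr(x, "residual")))
  invisible(x)
}

#' Export a flow ledger as a DOT graph description
#'
#' Writes the inferred flows as a Graphviz digraph (edge labels are flows in
#' % of the applied tracer) for rendering schematic flow diagrams.
#'
#' @param ledger A [infer_flows()] result.
#' @param path Optional file path; when `NULL` the DOT source is returned as
#'   a character string.
#' @param digits Rounding for edge labels.
#' @return The DOT source, invisibly when written to a file.
#' @export
flows_to_dot <- function(ledger, path = NULL, digits = 2) {
  stopifnot(inherits(ledger, "flow_ledger"))
  lines <- c(
    "digraph tracer_flows {",
    "  rankdir=TB;",
    "  node [shape=box];",
    sprintf('  "%s" -> "%s" [label="%s"];', ledger$from, ledger$to,
            formatC(round(ledger$flow, digits), format = "fg")),
    "}")
  src <- paste(lines, collapse = "\n")
  if (is.null(path)) return(src)
  writeLines(src, path)
  invisible(src)
}
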