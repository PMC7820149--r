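#' Construct an energy-flow network
#'
#' A `flow_network` is a snapshot, steady-state representation of an
#' ecosystem energy budget: a set of compartments (taxa and detritus pools)
#' with boundary flows, plus a square matrix of internal transfers.
#' Currency is joules of energy; flows are J/m^2/yr, storages J/m^2.
#'
#' @param nodes data.frame with columns `name` (unique character),
#'   `living` (logical), `storage` (J/m^2), `input` (boundary inflow,
#'   J/m^2/yr), `export` (non-respiratory boundary outflow, J/m^2/yr) and
#'   `respiration` (dissipative outflow, J/m^2/yr). Non-living compartments
#'   must have zero respiration.
#' @param flows square numeric matrix; `flows[i, j]` is the internal flow
#'   from node `i` (donor) to node `j` (recipient) in J/m^2/yr. The
#'   diagonal must be zero. Dimnames, if present, must match `nodes$name`.
#'
#' @return An object of class `flow_network`: a list with elements
#'   `nodes` (data.frame, row order preserved) and `F` (flow matrix with
#'   node names as dimnames).
#'
#' @details All flows and storages must be nonnegative. The donor-oriented
#' (row = source) matrix convention is shared by every analysis function in
#' the package.
#'
#' @examples
#' net <- flow_network(
#'   nodes = data.frame(
#'     name = c("A", "B"), living = TRUE, storage = c(200, 100),
#'     input = c(100, 0), export = c(20, 10), respiration = c(30, 40)
#'   ),
#'   flows = matrix(c(0, 50, 0, 0), 2, 2, byrow = TRUE)
#' )
#' steady_state_residuals(net)
#' @export
flow_network <- function(nodes, flows) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  required <- c("name", "living", "storage", "input", "export", "respiration")
  missing <- setdiff(required, names(nodes))
  if (length(missing)) {
    stop("nodes is missing column(s): ", paste(missing, collapse = ", "))
  }
  nodes <- nodes[required]
  nodes$name <- as.character(nodes$name)
  nodes$living <- as.logical(nodes$living)
  if (anyNA(nodes$living)) stop("nodes$living must be TRUE/FALSE")
  if (anyDuplicated(nodes$name)) {
    stop("duplicate node names: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  }
  n <- nrow(nodes)
  flows <- as.matrix(flows)
  if (n == 0L) {
    flows <- matrix(numeric(0), 0, 0)
  }
  if (!is.numeric(flows) && n > 0L) stop("flows must be numeric")
  if (nrow(flows) != n || ncol(flows) != n) {
    stop("flows must be a ", n, " x ", n, " matrix to match the node table")
  }
  if (!is.null(rownames(flows)) && !identical(rownames(flows), nodes$name)) {
    stop("flow matrix dimnames do not match node names")
  }
  num_cols <- c("storage", "input", "export", "respiration")
  for (col in num_cols) {
    if (n == 0L) nodes[[col]] <- numeric(0)
    v <- nodes[[col]]
    if (!is.numeric(v) || anyNA(v)) stop("nodes$", col, " must be numeric and non-missing")
    if (any(v < 0)) stop("nodes$", col, " has negative values")
  }
  if (n > 0) {
    if (anyNA(flows)) stop("flows contains missing values")
    if (any(flows < 0)) stop("flows has negative entries")
    if (any(diag(flows) != 0)) stop("flow matrix diagonal must be zero (no self-flows)")
    if (any(nodes$respiration[!nodes$living] > 0)) {
      stop("non-living compartments must have zero respiration")
    }
    dimnames(flows) <- list(nodes$name, nodes$name)
  }
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, F = flows), class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  n <- nrow(x$nodes)
  nlinks <- sum(x$F > 0)
  cat("flow_network:", n, "nodes,", nlinks, "internal links\n")
  cat("  total boundary input:", format(sum(x$nodes$input)), "J/m2/yr\n")
  cat("  total export:", format(sum(x$nodes$export)),
      " total respiration:", format(sum(x$nodes$respiration)), "J/m2/yr\n")
  invisible(x)
}

n_nodes <- function(net) nrow(net$nodes)

stopifnot_flow_network <- function(net) {
  if (!inherits(net, "flow_network")) stop("expected a flow_network object")
  invisible(net)
}

#' Read a flow network from node and flow CSV files
#'
#' @param nodes_path CSV with columns name,living,storage,input,export,respiration.
#' @param flows_path CSV with columns source,target,flow (one row per
#'   realized internal link; omitted pairs are zero).
#' @return A [flow_network]. Node order follows the node file.
#' @export
read_network <- function(nodes_path, flows_path) {
  nodes <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(flows_path, stringsAsFactors = FALSE)
  need <- setdiff(c("source", "target", "flow"), names(edges))
  if (length(need)) stop("flows file missing column(s): ", paste(need, collapse = ", "))
  if (!"name" %in% names(nodes)) stop("nodes file missing 'name' column")
  n <- nrow(nodes)
  F <- matrix(0, n, n, dimnames = list(nodes$name, nodes$name))
  if (nrow(edges)) {
    unknown <- setdiff(unique(c(edges$source, edges$target)), nodes$name)
    if (length(unknown)) {
      stop("flow file references node(s) absent from the node file: ",
           paste(unknown, collapse = ", "))
    }
    if (any(edges$flow < 0)) stop("negative flow values in ", flows_path)
    for (k in seq_len(nrow(edges))) {
      F[edges$source[k], edges$target[k]] <- F[edges$source[k], edges$target[k]] + edges$flow[k]
    }
  }
  flow_network(nodes, F)
}

#' Write a flow network to node and flow CSV files
#'
#' Values are rendered with 15 significant digits so a read/write round
#' trip reproduces the network.
#'
#' @param net a [flow_network].
#' @param nodes_path,flows_path output paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, nodes_path, flows_path) {
  stopifnot_flow_network(net)
  nd <- net$nodes
  for (col in c("storage", "input", "export", "respiration")) {
    nd[[col]] <- format(nd[[col]], digits = 15, scientific = FALSE, trim = TRUE)
  }
  utils::write.csv(nd, nodes_path, row.names = FALSE, quote = FALSE)
  idx <- which(net$F > 0, arr.ind = TRUE)
  edges <- data.frame(
    source = net$nodes$name[idx[, 1]],
    target = net$nodes$name[idx[, 2]],
    flow = format(net$F[idx], digits = 15, scientific = FALSE, trim = TRUE)
  )
  utils::write.csv(edges, flows_path, row.names = FALSE, quote = FALSE)
  invisible(net)
}

#' Steady-state mass-balance diagnostics
#'
#' For each compartment the residual is inflow minus outflow:
#' `input + colSums(F)` minus `export + respiration + rowSums(F)`. A
#' balanced (steady-state) network has all residuals zero; the matrix
#' analyses in this package assume that state.
#'
#' @param net a [flow_network].
#' @param tol relative tolerance used only to set the `converged` flag.
#' @return A `balance_report`: data.frame of per-node `residual` and
#'   `relative` residual (residual over inflow-based throughflow), with
#'   attributes `method`, `iterations` and `converged`.
#' @export
steady_state_residuals <- function(net, tol = 1e-6) {
  stopifnot_flow_network(net)
  inflow <- net$nodes$input + colSums(net$F)
  outflow <- net$nodes$export + net$nodes$respiration + rowSums(net$F)
  residual <- inflow - outflow
  rel <- ifelse(inflow > 0, residual / inflow, ifelse(residual == 0, 0, Inf))
  balance_report(net$nodes$name, residual, rel, method = "diagnostic",
                 iterations = 0L, tol = tol)
}

balance_report <- function(names, residual, relative, method, iterations, tol) {
  rep <- data.frame(node = names, residual = residual, relative = relative,
                    stringsAsFactors = FALSE)
  attr(rep, "method") <- method
  attr(rep, "iterations") <- iterations
  attr(rep, "tol") <- tol
  attr(rep, "converged") <- length(relative) == 0 || max(abs(relative)) <= tol
  class(rep) <- c("balance_report", "data.frame")
  rep
}

#' @export
print.balance_report <- function(x, ...) {
  cat("balance_report [", attr(x, "method"), "] iterations:",
      attr(x, "iterations"),
      " converged:", attr(x, "converged"), "\n")
  if (nrow(x)) {
    cat("  max |relative residual|:",
        format(max(abs(x$relative)), digits = 4), "\n")
  }
  invisible(x)
}

#' Balance a flow network to steady state (AVG2-style flow scaling)
#'
#' Iteratively rescales internal flows until every compartment's inflow
#' matches its outflow. Each iteration performs an input-scaling pass
#' (each node's internal inflow column is rescaled to meet its outflow
#' total) and an output-scaling pass (each internal outflow row rescaled
#' to meet its inflow total) in both orders, then averages the two
#' resulting matrices element-wise. Boundary flows (input, export,
#' respiration) are treated as data and held fixed; only internal flows
#' move. The scheme is a member of the averaged input/output-scaling
#' family used for steady-state adjustment of ecosystem flow networks.
#'
#' @param net a [flow_network] with positive total boundary input.
#' @param tol convergence tolerance on the maximum relative residual.
#' @param max_iter iteration cap; non-convergence is reported via the
#'   `converged` flag, not an error.
#' @return list with elements `network` (balanced [flow_network]) and
#'   `report` (a `balance_report`).
#' @export
balance_avg2 <- function(net, tol = 1e-6, max_iter = 1000L) {
  stopifnot_flow_network(net)
  n <- n_nodes(net)
  if (n == 0L) {
    return(list(network = net,
                report = balance_report(character(0), numeric(0), numeric(0),
                                        "avg2-io-oi-mean", 0L, tol)))
  }
  if (sum(net$nodes$input) <= 0) stop("balance_avg2 requires positive total boundary input")
  z <- net$nodes$input
  ex <- net$nodes$export
  rs <- net$nodes$respiration
  F <- net$F

  max_rel <- function(F) {
    inflow <- z + colSums(F)
    resid <- inflow - (ex + rs + rowSums(F))
    rel <- ifelse(inflow > 0, abs(resid) / inflow, ifelse(resid == 0, 0, Inf))
    max(rel)
  }
  # a node with no internal flows at all cannot be adjusted: its boundary
  # terms must already balance
  throughflow0 <- rowSums(F) + colSums(F)
  resid0 <- (z + colSums(F)) - (ex + rs + rowSums(F))
  stuck <- throughflow0 == 0 & abs(resid0) > tol * pmax(1, z)
  if (any(stuck)) {
    stop("node(s) with zero throughflow but nonzero imbalance: ",
         paste(net$nodes$name[stuck], collapse = ", "))
  }
  # rescale internal inflow columns so inflow total meets outflow total
  scale_in <- function(F) {
    target <- ex + rs + rowSums(F) - z          # required internal inflow
    have <- colSums(F)
    for (j in seq_len(n)) {
      if (have[j] > 0) F[, j] <- F[, j] * max(target[j], 0) / have[j]
    }
    F
  }
  # rescale internal outflow rows so outflow total meets inflow total
  scale_out <- function(F) {
    target <- z + colSums(F) - ex - rs          # required internal outflow
    have <- rowSums(F)
    for (i in seq_len(n)) {
      if (have[i] > 0) F[i, ] <- F[i, ] * max(target[i], 0) / have[i]
    }
    F
  }

  iter <- 0L
  while (max_rel(F) > tol && iter < max_iter) {
    F_io <- scale_out(scale_in(F))
    F_oi <- scale_in(scale_out(F))
    F <- (F_io + F_oi) / 2
    iter <- iter + 1L
  }
  out <- net
  out$F <- F
  inflow <- z + colSums(F)
  resid <- inflow - (ex + rs + rowSums(F))
  rel <- ifelse(inflow > 0, resid / inflow, ifelse(resid == 0, 0, Inf))
  list(network = out,
       report = balance_report(net$nodes$name, resid, rel,
                               "avg2-io-oi-mean", iter, tol))
}

#' Weighted-web connectance
#'
#' The fraction of possible directed links that carry flow: `L / S^2`,
#' where `L` is the number of strictly positive internal flows and `S` the
#' number of compartments (living and non-living alike).
#'
#' @param net a [flow_network] with at least one node.
#' @return a single number in `[0, 1]`.
#' @export
connectance <- function(net) {
  stopifnot_flow_network(net)
  S <- n_nodes(net)
  if (S < 1) stop("connectance needs at least one node")
  sum(net$F > 0) / S^2
}
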