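#' Per-node throughflow
#'
#' Throughflow of a compartment is the total energy passing through it per
#' unit time: boundary input plus internal inflows (which, at steady
#' state, equals its total outflow). The sum over compartments is total
#' system throughflow (TST), the standard measure of system activity.
#'
#' @param net a balanced [flow_network].
#' @param tol relative imbalance above which a warning is raised.
#' @return named numeric vector of throughflows (J/m^2/yr).
#' @export
node_throughflow <- function(net, tol = 1e-6) {
  stopifnot_flow_network(net)
  T_in <- net$nodes$input + colSums(net$F)
  T_out <- net$nodes$export + net$nodes$respiration + rowSums(net$F)
  gap <- abs(T_in - T_out)
  bad <- T_in > 0 & gap / pmax(T_in, .Machine$double.xmin) > tol
  if (any(bad)) {
    warning("node(s) out of balance beyond tolerance: ",
            paste(net$nodes$name[bad], collapse = ", "),
            "; throughflow uses the inflow side")
  }
  stats::setNames(T_in, net$nodes$name)
}

#' Boundary / direct / indirect partition of system flow
#'
#' Forms the output-oriented dimensionless flow matrix `G` (flows divided
#' by donor throughflow) and its input-oriented counterpart `Gp` (flows
#' divided by recipient throughflow), inverts `I - G` to obtain the
#' integral flow matrix `Nout` (and `Nin` from `Gp`), and partitions total
#' system throughflow into the fractions attributable to boundary input
#' (BFI), direct transfers (DFI) and indirect transfers through
#' intermediaries (IFI). With input vector `z`:
#' `TST = z' Nout 1`, `BFI = sum(z)/TST`, `DFI = z' G 1 / TST`,
#' `IFI = z' (Nout - I - G) 1 / TST`, and the three fractions sum to one.
#' Network aggradation (`APL`), the mean number of compartments a joule
#' visits, is `TST / sum(z)`.
#'
#' Rows of `G` (columns of `Gp`) for compartments with zero throughflow
#' are set to zero, so inert nodes stay in the indexing without affecting
#' the partition.
#'
#' @param net a balanced [flow_network].
#' @return object of class `flow_partition`: list with `T`, `TST`,
#'   `total_respiration`, `total_exports`, `TSS`, `APL`, `G`, `Gp`,
#'   `Nout`, `Nin`, `BFI`, `DFI`, `IFI`.
#' @export
flow_partition <- function(net) {
  stopifnot_flow_network(net)
  T <- suppressWarnings(node_throughflow(net))
  n <- length(T)
  if (n == 0) stop("flow_partition needs at least one node")
  Tsafe <- ifelse(T > 0, T, 1)
  G <- net$F / Tsafe                 # row i divided by T_i (donor-normalized)
  Gp <- t(t(net$F) / Tsafe)          # column j divided by T_j
  G[T == 0, ] <- 0
  Gp[, T == 0] <- 0
  rho <- max(Mod(eigen(G, only.values = TRUE)$values))
  if (rho >= 1 - 1e-12) {
    stop("I - G is singular: spectral radius of G is ", format(rho))
  }
  I <- diag(n)
  Nout <- solve(I - G)
  Nin <- solve(I - Gp)
  z <- net$nodes$input
  TST <- sum(T)
  zsum <- sum(z)
  if (zsum <= 0) stop("flow_partition requires positive total boundary input")
  BFI <- zsum / TST
  DFI <- sum(z %*% G) / TST
  IFI <- sum(z %*% (Nout - I - G)) / TST
  structure(list(
    T = T, TST = TST,
    total_respiration = sum(net$nodes$respiration),
    total_exports = sum(net$nodes$export),
    TSS = sum(net$nodes$storage),
    APL = TST / zsum,
    G = G, Gp = Gp, Nout = Nout, Nin = Nin,
    BFI = BFI, DFI = DFI, IFI = IFI
  ), class = "flow_partition")
}

matrix_cv <- function(M) {
  v <- as.vector(M)
  m <- mean(v)
  if (m == 0) stop("matrix has zero mean; coefficient of variation undefined")
  stats::sd(v) / m
}

#' Network homogenization
#'
#' Ratio of the coefficient of variation of the direct (dimensionless)
#' flow matrix to that of the integral flow matrix. Values above one mean
#' the integral (direct plus indirect) flow distribution is more even than
#' the direct one: indirect pathways homogenize who-gets-what-from-whom.
#' The CV uses the sample (n-1) standard deviation over all S^2 entries,
#' zeros included.
#'
#' @param net a balanced [flow_network].
#' @param orientation `"input"` compares `Gp` to `Nin` (energy received);
#'   `"output"` compares `G` to `Nout`.
#' @return a single nonnegative number.
#' @export
homogenization <- function(net, orientation = c("input", "output")) {
  orientation <- match.arg(orientation)
  fp <- flow_partition(net)
  if (orientation == "input") {
    matrix_cv(fp$Gp) / matrix_cv(fp$Nin)
  } else {
    matrix_cv(fp$G) / matrix_cv(fp$Nout)
  }
}

#' Ascendency, development capacity and relative ascendency
#'
#' Information-theoretic measures of flow organization computed on the
#' network's extended flow matrix: the internal flows augmented with one
#' virtual import row (boundary inputs), one virtual export column and one
#' virtual dissipation column (respiration). With `T..` the total of all
#' entries, ascendency is `A = sum T_ij log2(T_ij T.. / (T_i. T_.j))` and
#' development capacity `C = -sum T_ij log2(T_ij / T..)`, both over
#' positive entries. Relative ascendency `A/C` lies in `[0, 1]` and is
#' independent of the logarithm base; high values indicate constrained,
#' specialized flow, low values a web of generalists.
#'
#' @param net a balanced [flow_network].
#' @param base logarithm base for the reported `A` and `Cdev` (default 2,
#'   i.e. flow-bits); `rel_ascendency` does not depend on it.
#' @return list with `A`, `Cdev`, `rel_ascendency`.
#' @export
ascendency_suite <- function(net, base = 2) {
  stopifnot_flow_network(net)
  n <- n_nodes(net)
  if (n == 0) stop("ascendency is undefined for an empty network")
  Text <- matrix(0, n + 3, n + 3)
  Text[seq_len(n), seq_len(n)] <- net$F
  Text[n + 1, seq_len(n)] <- net$nodes$input       # virtual import row
  Text[seq_len(n), n + 2] <- net$nodes$export      # virtual export column
  Text[seq_len(n), n + 3] <- net$nodes$respiration # virtual dissipation column
  tot <- sum(Text)
  if (tot <= 0) stop("network has zero total flow")
  ri <- rowSums(Text)
  cj <- colSums(Text)
  pos <- which(Text > 0, arr.ind = TRUE)
  tij <- Text[pos]
  A <- sum(tij * log(tij * tot / (ri[pos[, 1]] * cj[pos[, 2]]), base = base))
  Cdev <- -sum(tij * log(tij / tot, base = base))
  list(A = A, Cdev = Cdev, rel_ascendency = A / Cdev)
}

#' Network utility analysis: flow-based synergism and mutualism
#'
#' The direct utility matrix `D` holds net pairwise exchanges scaled by
#' the first party's throughflow: `d_ij = (F_ij - F_ji) / T_i`. When the
#' spectral radius of `D` is below one the power series converges and the
#' integral utility matrix is `U = (I - D)^-1`, accumulating direct and
#' indirect costs and benefits. `Y = diag(T) U` puts utilities back on the
#' flow scale. Network synergism is the benefit/cost ratio
#' `sum(Y+)/|sum(Y-)|` (non-obligatory positive feedback); network
#' mutualism is the ratio of the counts of positive to negative entries
#' (obligatory positive feedback). Exact zeros are excluded from the sign
#' counts; with no negative entries both ratios are `Inf`.
#'
#' @param net a balanced [flow_network].
#' @return object of class `utility_result`: list with `D`, `rho`,
#'   `convergent`, and (when convergent) `U`, `Y`, `synergism_F`,
#'   `mutualism_F` plus `mutualism_U`, the dimensionless-sign variant
#'   counted on `U`.
#' @export
utility_suite <- function(net) {
  stopifnot_flow_network(net)
  T <- suppressWarnings(node_throughflow(net))
  n <- length(T)
  Tsafe <- ifelse(T > 0, T, 1)
  D <- (net$F - t(net$F)) / Tsafe
  D[T == 0, ] <- 0
  rho <- if (n) max(Mod(eigen(D, only.values = TRUE)$values)) else 0
  res <- list(D = D, rho = rho, convergent = rho < 1,
              U = NULL, Y = NULL,
              synergism_F = NA_real_, mutualism_F = NA_real_,
              mutualism_U = NA_real_)
  if (res$convergent) {
    U <- solve(diag(n) - D)
    Y <- T * U                       # diag(T) %*% U
    sign_ratio <- function(M) {
      npos <- sum(M > 0); nneg <- sum(M < 0)
      if (nneg == 0) Inf else npos / nneg
    }
    neg <- sum(Y[Y < 0])
    res$U <- U
    res$Y <- Y
    res$synergism_F <- if (neg == 0) Inf else sum(Y[Y > 0]) / abs(neg)
    res$mutualism_F <- sign_ratio(Y)
    res$mutualism_U <- sign_ratio(U)
  }
  class(res) <- "utility_result"
  res
}

#' Average environ centrality
#'
#' A compartment's share of total direct-plus-indirect flow involvement.
#' Output environ centrality is its share of the row sums of the integral
#' output matrix `Nout`; input environ centrality its share of the column
#' sums of `Nin`; the average environ centrality (AEC) is their mean.
#' Each vector sums to one, so AEC is comparable across webs of different
#' size and activity.
#'
#' @param net a balanced [flow_network].
#' @return list with named vectors `EC_out`, `EC_in`, `AEC`.
#' @export
environ_centrality <- function(net) {
  fp <- flow_partition(net)
  EC_out <- rowSums(fp$Nout) / sum(fp$Nout)
  EC_in <- colSums(fp$Nin) / sum(fp$Nin)
  AEC <- (EC_out + EC_in) / 2
  nm <- net$nodes$name
  list(EC_out = stats::setNames(EC_out, nm),
       EC_in = stats::setNames(EC_in, nm),
       AEC = stats::setNames(AEC, nm))
}

#' Full network-metric summary
#'
#' Computes the ten web-level metrics reported for each site web — total
#' system throughflow (TST), respiration flows (Resp), export flows
#' (Exports), network aggradation (NetAgg), indirect flow intensity
#' (IFI), input homogenization (HmgInput), relative ascendency (RelAsc),
#' total system storage (TSS), flow-based mutualism (MutFlow) and
#' flow-based synergism (SynFlow) — plus the average environ centrality
#' vector. Failures in one sub-metric are recorded and the remaining
#' metrics still returned.
#'
#' @param net a balanced [flow_network].
#' @return object of class `ena_summary`: list with `metrics` (named
#'   numeric vector of the ten metrics), `AEC`, `partition`, `utility`,
#'   `errors` (named character vector of sub-metric failures, if any).
#' @export
ena_summary <- function(net) {
  stopifnot_flow_network(net)
  metrics <- c(TST = NA_real_, Resp = NA_real_, Exports = NA_real_,
               NetAgg = NA_real_, IFI = NA_real_, HmgInput = NA_real_,
               RelAsc = NA_real_, TSS = NA_real_, MutFlow = NA_real_,
               SynFlow = NA_real_)
  errors <- character(0)
  grab <- function(expr, label) {
    tryCatch(expr, error = function(e) {
      errors[[label]] <<- conditionMessage(e)
      NULL
    })
  }
  fp <- grab(flow_partition(net), "flow_partition")
  if (!is.null(fp)) {
    metrics["TST"] <- fp$TST
    metrics["Resp"] <- fp$total_respiration
    metrics["Exports"] <- fp$total_exports
    metrics["NetAgg"] <- fp$APL
    metrics["IFI"] <- fp$IFI
    metrics["TSS"] <- fp$TSS
    metrics["HmgInput"] <- grab(matrix_cv(fp$Gp) / matrix_cv(fp$Nin),
                                "homogenization") %||% NA_real_
  }
  asc <- grab(ascendency_suite(net), "ascendency")
  if (!is.null(asc)) metrics["RelAsc"] <- asc$rel_ascendency
  ut <- grab(utility_suite(net), "utility")
  if (!is.null(ut) && ut$convergent) {
    metrics["MutFlow"] <- ut$mutualism_F
    metrics["SynFlow"] <- ut$synergism_F
  } else if (!is.null(ut)) {
    errors[["utility"]] <- paste0("utility series divergent (rho = ",
                                  format(ut$rho), ")")
  }
  aec <- if (!is.null(fp)) {
    EC_out <- rowSums(fp$Nout) / sum(fp$Nout)
    EC_in <- colSums(fp$Nin) / sum(fp$Nin)
    stats::setNames((EC_out + EC_in) / 2, net$nodes$name)
  } else NULL
  structure(list(metrics = metrics, AEC = aec, partition = fp,
                 utility = ut, ascendency = asc, errors = errors),
            class = "ena_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ena_summary <- function(x, ...) {
  cat("ena_summary (ten web-level metrics):\n")
  print(round(x$metrics, 4))
  if (length(x$errors)) {
    cat("sub-metric errors:\n")
    for (nm in names(x$errors)) cat("  ", nm, ": ", x$errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}
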