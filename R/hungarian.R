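#' Minimum-cost bipartite assignment (Hungarian algorithm)
#'
#' Solves the rectangular linear sum assignment problem by shortest
#' augmenting paths (Jonker-Volgenant). All `min(Np, Nq)` assignments are
#' returned; with a rectangular matrix the surplus rows or columns stay
#' unmatched. No distance gating is applied -- arbitrarily costly pairs are
#' still assigned, which is exactly the behaviour the cross-check evaluation
#' metric guards against.
#'
#' @param cost numeric matrix of finite, non-negative costs (may be
#'   rectangular or empty).
#' @return Integer matrix with columns `row`, `col` (1-based), one row per
#'   assigned pair, ordered by `row`; zero rows when either side is empty.
#' @export
#' @examples
#' hungarian_assign(rbind(c(1, 10), c(10, 1)))
hungarian_assign <- function(cost) {
  cost <- as.matrix(cost)
  nr <- nrow(cost); nc <- ncol(cost)
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("row", "col")))
  if (nr == 0 || nc == 0) return(empty)
  stopifnot(all(is.finite(cost)), all(cost >= 0))
  transposed <- nr > nc
  if (transposed) { cost <- t(cost); tmp <- nr; nr <- nc; nc <- tmp }

  u <- numeric(nr); v <- numeric(nc)
  col4row <- rep(-1L, nr); row4col <- rep(-1L, nc)
  for (cur in seq_len(nr)) {
    # Dijkstra over the residual graph rooted at row `cur`
    shortest <- rep(Inf, nc)
    path <- rep(-1L, nc)
    remaining <- rep(TRUE, nc)
    in_sr <- rep(FALSE, nr)
    min_val <- 0
    i <- cur
    sink <- -1L
    while (sink == -1L) {
      in_sr[i] <- TRUE
      idx <- which(remaining)
      red <- min_val + cost[i, idx] - u[i] - v[idx]
      upd <- red < shortest[idx]
      if (any(upd)) {
        shortest[idx[upd]] <- red[upd]
        path[idx[upd]] <- i
      }
      j <- idx[which.min(shortest[idx])]
      min_val <- shortest[j]
      if (!is.finite(min_val)) stop("infeasible assignment problem")
      remaining[j] <- FALSE
      if (row4col[j] == -1L) sink <- j else i <- row4col[j]
    }
    # update dual potentials
    u[cur] <- u[cur] + min_val
    upd_rows <- which(in_sr & seq_len(nr) != cur)
    if (length(upd_rows)) {
      u[upd_rows] <- u[upd_rows] + min_val - shortest[col4row[upd_rows]]
    }
    scanned <- which(!remaining)
    v[scanned] <- v[scanned] - (min_val - shortest[scanned])
    # augment along the alternating path
    j <- sink
    repeat {
      i <- path[j]
      row4col[j] <- i
      prev <- col4row[i]
      col4row[i] <- j
      if (i == cur) break
      j <- prev
    }
  }
  out <- cbind(row = seq_len(nr), col = col4row)
  if (transposed) out <- cbind(row = out[, "col"], col = out[, "row"])
  out <- out[order(out[, "row"]), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}
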