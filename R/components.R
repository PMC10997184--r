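# Connected components under 4-connectivity, by iterative minimum-label
# propagation on the bounding box of the foreground. Pure R: slice-sized
# problems (<= 512 px) converge in tens of milliseconds and need no
# compiled code.

# bw: logical matrix. Returns integer matrix of component labels (0 =
# background); labels are 1..k ordered by decreasing component size, ties by
# smallest linear pixel index (deterministic).
connectedComponents <- function(bw) {
  out <- matrix(0L, nrow(bw), ncol(bw))
  if (!any(bw)) return(out)
  rows <- range(which(rowSums(bw) > 0))
  cols <- range(which(colSums(bw) > 0))
  sub <- bw[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  h <- nrow(sub); w <- ncol(sub)
  lab <- matrix(0L, h, w)
  lab[sub] <- seq_len(sum(sub))  # unique seed labels, column-major order
  big <- .Machine$integer.max
  lab[!sub] <- big
  repeat {
    up    <- rbind(lab[-1, , drop = FALSE], rep(big, w))
    down  <- rbind(rep(big, w), lab[-h, , drop = FALSE])
    left  <- cbind(lab[, -1, drop = FALSE], rep(big, h))
    right <- cbind(rep(big, h), lab[, -w, drop = FALSE])
    nl <- pmin(lab, up, down, left, right)
    nl[!sub] <- big
    if (identical(nl, lab)) break
    lab <- nl
  }
  lab[!sub] <- 0L
  ids <- sort(unique(lab[lab > 0L]))
  sizes <- tabulate(match(lab[lab > 0L], ids))
  ord <- order(-sizes, ids)  # big first; ties by earliest seed (lowest index)
  remap <- integer(length(ids)); remap[ord] <- seq_along(ids)
  lab[lab > 0L] <- remap[match(lab[lab > 0L], ids)]
  out[rows[1]:rows[2], cols[1]:cols[2]] <- lab
  out
}

componentSizes <- function(cc) {
  k <- max(cc)
  if (k == 0L) return(integer(0))
  tabulate(cc[cc > 0L], nbins = k)
}
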