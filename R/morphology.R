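# Small self-contained 3D binary morphology on logical arrays, built from
# zero-padded array shifts (6-connectivity). Sufficient for the "rough brain
# contour" cleanup; not a general morphology library.

shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(FALSE, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  kx <- fx >= 1 & fx <= d[1]; ky <- fy >= 1 & fy <= d[2]; kz <- fz >= 1 & fz <= d[3]
  out[sx[kx], sy[ky], sz[kz]] <- a[fx[kx], fy[ky], fz[kz]]
  out
}

dilate6 <- function(mask, iter = 1L) {
  for (i in seq_len(iter)) {
    mask <- mask |
      shift3(mask, 1, 0, 0) | shift3(mask, -1, 0, 0) |
      shift3(mask, 0, 1, 0) | shift3(mask, 0, -1, 0) |
      shift3(mask, 0, 0, 1) | shift3(mask, 0, 0, -1)
  }
  mask
}

erode6 <- function(mask, iter = 1L) !dilate6(!mask, iter)

close6 <- function(mask, radius = 3L) erode6(dilate6(mask, radius), radius)

# flood: grow seed within mask until fixed point (6-connectivity)
flood6 <- function(seed, mask) {
  cur <- seed & mask
  repeat {
    nxt <- (dilate6(cur, 1L) & mask) | cur
    if (sum(nxt) == sum(cur)) return(cur)
    cur <- nxt
  }
}

fill_holes3 <- function(mask) {
  d <- dim(mask)
  border <- array(FALSE, d)
  border[c(1, d[1]), , ] <- TRUE
  border[, c(1, d[2]), ] <- TRUE
  border[, , c(1, d[3])] <- TRUE
  outside <- flood6(border & !mask, !mask)
  mask | (!mask & !outside)
}

# connected components via max-label propagation; returns integer array
# (0 = background) and component sizes sorted decreasing
components6 <- function(mask) {
  lab <- array(0, dim(mask))
  lab[mask] <- seq_len(sum(mask))
  repeat {
    nxt <- pmax(lab,
                shift3a(lab, 1, 0, 0), shift3a(lab, -1, 0, 0),
                shift3a(lab, 0, 1, 0), shift3a(lab, 0, -1, 0),
                shift3a(lab, 0, 0, 1), shift3a(lab, 0, 0, -1))
    nxt[!mask] <- 0
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  sizes <- sort(table(lab[lab > 0]), decreasing = TRUE)
  list(labels = lab, sizes = sizes)
}

largest_component6 <- function(mask) {
  if (!any(mask)) return(mask)
  cc <- components6(mask)
  cc$labels == as.integer(names(cc$sizes)[1])
}

shift3a <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- seq_len(d[1]); sy <- seq_len(d[2]); sz <- seq_len(d[3])
  fx <- sx - dx; fy <- sy - dy; fz <- sz - dz
  kx <- fx >= 1 & fx <= d[1]; ky <- fy >= 1 & fy <= d[2]; kz <- fz >= 1 & fz <= d[3]
  out[sx[kx], sy[ky], sz[kz]] <- a[fx[kx], fy[ky], fz[kz]]
  out
}
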