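# Shared helpers: seeded evaluation, 8-connected labeling, boundary sets.

#' Evaluate an expression under a temporary Mersenne-Twister seed
#'
#' Saves and restores the caller's RNG state, so pipeline functions are
#' deterministic given their configured seeds without disturbing the user's
#' random stream.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "Mersenne-Twister")
  expr
}

#' 8-connected component labeling
#'
#' EBImage's labeler is 4-connected; diffraction-limited foci and island
#' masks are treated as 8-connected here, so 4-connected labels touching
#' diagonally are merged with a small union-find over the label graph.
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @noRd
.label8 <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  l4 <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  nlab <- max(l4)
  if (nlab <= 1L) return(l4)
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  nr <- nrow(l4); nc <- ncol(l4)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    dr <- sh[1L]; dc <- sh[2L]
    r1 <- seq_len(nr - dr); c1 <- if (dc > 0) seq_len(nc - dc) else seq(1L - dc, nc)
    a <- l4[r1, c1, drop = FALSE]
    b <- l4[r1 + dr, c1 + dc, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) {
      pr <- unique(cbind(a[sel], b[sel]))
      for (i in seq_len(nrow(pr))) {
        ra <- find(pr[i, 1L]); rb <- find(pr[i, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(nlab), find, integer(1))
  new_id <- integer(nlab)
  new_id[sort(unique(roots))] <- seq_along(unique(roots))
  out <- l4
  out[l4 > 0L] <- new_id[roots[l4[l4 > 0L]]]
  out
}

#' Boundary pixels of a mask: mask pixels 4-adjacent to a non-mask pixel
#' (pixels on the image edge count as boundary).
#' @return logical matrix.
#' @noRd
.boundary4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
              pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  mask & !interior
}

#' Clamp-free stable per-island seed derived from a base seed
#' @noRd
.substream_seed <- function(base_seed, index) {
  (as.numeric(base_seed) + 1000003 * as.numeric(index)) %% 2147483647
}
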