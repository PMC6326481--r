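# Shared fixtures and independent oracles used across the suite.

unit_square <- function(side = 10, at = c(0, 0), id = NULL) {
  patch_polygon(cbind(at[1] + c(0, side, side, 0),
                      at[2] + c(0, 0, side, side)), id = id)
}

# plus-shaped pentomino of five 1 m cells; hand geometry:
# area 5, perimeter 12, 12 nodes, hull area 7, hull perimeter 4 + 4*sqrt(2)
plus_pentomino <- function() {
  patch_polygon(cbind(c(1, 2, 2, 3, 3, 2, 2, 1, 1, 0, 0, 1),
                      c(0, 0, 1, 1, 2, 2, 3, 3, 2, 2, 1, 1)))
}

random_star <- function(k = 12, rough = 0.4, r0 = 10, at = c(0, 0)) {
  th <- sort(runif(k, 0, 2 * pi))
  r <- r0 * (1 + rough * runif(k, -1, 1))
  patch_polygon(cbind(at[1] + r * cos(th), at[2] + r * sin(th)), check = FALSE)
}

# --- independent rectilinear oracle -------------------------------------
# A random 4-connected cell blob plus closed-form cell/edge/corner
# counting, against which traced polygons are checked.

random_blob <- function(n_cells = 30, grid = 12) {
  cells <- matrix(c(grid %/% 2, grid %/% 2), 1, 2)
  occ <- matrix(FALSE, grid, grid)
  occ[cells[1, 1], cells[1, 2]] <- TRUE
  while (nrow(cells) < n_cells) {
    base <- cells[sample(nrow(cells), 1), ]
    step <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[sample(4, 1), ]
    cand <- base + step
    if (any(cand < 1) || any(cand > grid) || occ[cand[1], cand[2]]) next
    occ[cand[1], cand[2]] <- TRUE
    cells <- rbind(cells, cand)
  }
  occ
}

# boundary edge count of a cell mask (perimeter in cell units)
blob_perimeter <- function(occ) {
  nr <- nrow(occ); nc <- ncol(occ)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- occ
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  sum(core & !pad[1:nr, 2:(nc + 1)]) + sum(core & !pad[3:(nr + 2), 2:(nc + 1)]) +
    sum(core & !pad[2:(nr + 1), 1:nc]) + sum(core & !pad[2:(nr + 1), 3:(nc + 2)])
}

# corner (node) count over all boundary loops: classify every 2x2
# window of the padded mask; windows with 1 or 3 set cells contribute
# one corner, diagonal windows contribute two.
blob_corners <- function(occ) {
  nr <- nrow(occ); nc <- ncol(occ)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- occ
  corners <- 0
  for (i in 1:(nr + 1)) for (j in 1:(nc + 1)) {
    w <- pad[i:(i + 1), j:(j + 1)]
    s <- sum(w)
    if (s == 1 || s == 3) corners <- corners + 1
    else if (s == 2 && w[1, 1] == w[2, 2] && w[1, 1] != w[1, 2])
      corners <- corners + 2
  }
  corners
}

# minimal two-epoch fixture builders for STAMP tests
square_layer <- function(squares, epoch = NA) {
  # squares: list of c(x, y, side)
  patch_layer(lapply(seq_along(squares), function(i) {
    s <- squares[[i]]
    unit_square(side = s[3], at = s[1:2], id = paste0("s", i))
  }), epoch = epoch, crs = "test-metric")
}

random_epoch_pair <- function(n_groups = 3) {
  # well-separated groups, random per-patch scripted change
  ax <- seq(0, by = 400, length.out = n_groups)
  pt <- list(); p1 <- list()
  for (g in seq_len(n_groups)) {
    ctr <- c(ax[g], runif(1, -50, 50))
    p <- random_star(k = 10, rough = 0.3, r0 = runif(1, 15, 40), at = ctr)
    ev <- sample(c("stable", "expand", "contract", "disappear", "generate"), 1)
    if (ev != "generate") pt[[length(pt) + 1L]] <- p
    if (ev %in% c("stable")) p1[[length(p1) + 1L]] <- p
    if (ev == "expand")
      p1[[length(p1) + 1L]] <- scale_patch(p, 1.3, centre = ctr)
    if (ev == "contract")
      p1[[length(p1) + 1L]] <- scale_patch(p, 0.7, centre = ctr)
    if (ev == "generate") p1[[length(p1) + 1L]] <- p
  }
  list(t = patch_layer(pt, epoch = 2004, crs = "test-metric"),
       t1 = patch_layer(p1, epoch = 2014, crs = "test-metric"))
}
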