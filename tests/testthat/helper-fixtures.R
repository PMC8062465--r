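# shared fixtures built in code

# characterized near-infra-red probe: pH_t 6.28, width 0.21, 111-fold
# OFF-ON activation, flat always-ON
reference_probe <- function() birn_probe()

reference_off_on <- function() {
  probe_module("Cy5", "off_on", f_max = 111, f_min = 1,
               ph_t = 6.28, width_10_90 = 0.21)
}

noiseless_curve <- function(probe = reference_probe()) {
  build_calibration(gen_calibration_plate(probe, noise = 0, seed = 1))
}

# independent connected-components oracle: pixel-adjacency graph
flood_fill_components <- function(mask, connectivity = 8) {
  on <- which(mask != 0)
  if (length(on) == 0L) return(0L)
  nr <- nrow(mask)
  pos <- cbind((on - 1L) %% nr, (on - 1L) %/% nr)
  edges <- NULL
  for (i in seq_along(on)) {
    dr <- abs(pos[, 1] - pos[i, 1]); dc <- abs(pos[, 2] - pos[i, 2])
    nb <- if (connectivity == 8) {
      which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
    } else {
      which(dr + dc == 1)
    }
    nb <- nb[nb > i]
    if (length(nb)) edges <- rbind(edges, cbind(i, nb))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# oracle component sizes (sorted), for min_area filtering comparisons
flood_fill_sizes <- function(mask, connectivity = 8) {
  on <- which(mask != 0)
  if (length(on) == 0L) return(integer(0))
  nr <- nrow(mask)
  pos <- cbind((on - 1L) %% nr, (on - 1L) %/% nr)
  edges <- NULL
  for (i in seq_along(on)) {
    dr <- abs(pos[, 1] - pos[i, 1]); dc <- abs(pos[, 2] - pos[i, 2])
    nb <- if (connectivity == 8) {
      which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
    } else {
      which(dr + dc == 1)
    }
    nb <- nb[nb > i]
    if (length(nb)) edges <- rbind(edges, cbind(i, nb))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  sort(igraph::components(g)$csize)
}
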