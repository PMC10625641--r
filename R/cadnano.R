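#' Import a caDNAno design (simplified)
#'
#' Reads the square- or honeycomb-lattice caDNAno JSON dialect and converts
#' it to the node/element representation: every base position occupied by the
#' scaffold becomes a base-pair node; consecutive occupied positions within a
#' helix become step elements; scaffold or staple strand exchanges between
#' helices become crossover elements. Designs using loops or skips
#' (insertions/deletions) are rejected.
#'
#' @param path Path to a caDNAno JSON file.
#' @param lattice "square" or "honeycomb" (geometry of the helix arrangement).
#' @param params Parameter table.
#' @return A [dna_structure()].
#' @export
read_cadnano <- function(path, lattice = c("square", "honeycomb"),
                         params = default_parameter_table()) {
  lattice <- match.arg(lattice)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  vs <- doc$vstrands
  if (is.null(vs) || length(vs) == 0) stop("no vstrands found in ", path)
  d <- params$helix_pitch; rise <- params$rise; twist <- params$twist
  get_arr <- function(v, name) lapply(v[[name]], function(x) unlist(x))
  nodes_key <- list(); pos <- NULL; quat <- NULL
  helix_of <- integer(0); idx_of <- integer(0)
  # first pass: create nodes at scaffold-occupied positions
  for (v in vs) {
    num <- v$num; row <- v$row; col <- v$col
    if (any(unlist(v$loop) != 0)) stop("caDNAno import: loops are not supported")
    if (any(unlist(v$skip) != 0)) stop("caDNAno import: skips are not supported")
    scaf <- get_arr(v, "scaf")
    origin <- if (lattice == "square") c(col * d, row * d)
    else c(col * d * sqrt(3) / 2, (row + 0.5 * (col %% 2)) * d)
    flip <- num %% 2 == 1
    for (i in seq_along(scaf)) {
      s <- scaf[[i]]
      if (all(s == -1)) next
      k <- length(helix_of) + 1L
      nodes_key[[paste(num, i - 1L)]] <- k
      helix_of[k] <- num; idx_of[k] <- i - 1L
      ang <- (i - 1L) * twist * pi / 180
      # antiparallel helices twist the other way along the global index so
      # that steps taken along each helix's own axis see +twist
      R <- if (flip) rot_x(pi) %*% rot_z(-ang) else rot_z(ang)
      pos <- rbind(pos, c(origin[1], origin[2], (i - 1L) * rise))
      quat <- rbind(quat, quat_from_matrix(R))
    }
  }
  if (is.null(pos)) stop("caDNAno import: no occupied scaffold positions")
  nodes <- make_nodes(pos, quat, "average", params)
  el <- empty_elements()
  Ks <- step_stiffness_matrix(params)
  Kx <- crossover_stiffness_matrix(params)
  # steps: consecutive scaffold-occupied positions within a helix
  for (k in seq_along(helix_of)) {
    nxt <- nodes_key[[paste(helix_of[k], idx_of[k] + 1L)]]
    if (!is.null(nxt)) {
      a <- k; b <- nxt
      if (helix_of[k] %% 2 == 1) { a <- nxt; b <- k } # follow the helix axis
      el <- add_element(el, "step", a, b,
                        intrinsic = c(0, 0, rise, 0, 0, twist), stiffness = Ks)
    }
  }
  # crossovers: scaffold or staple 3' connections jumping to another helix
  seen_x <- character(0)
  for (v in vs) {
    num <- v$num
    for (strand in c("scaf", "stap")) {
      arr <- get_arr(v, strand)
      for (i in seq_along(arr)) {
        s <- arr[[i]]
        if (all(s == -1)) next
        from <- nodes_key[[paste(num, i - 1L)]]
        if (is.null(from)) next
        h3 <- s[3]; i3 <- s[4]
        if (h3 == -1 || h3 == num) next
        to <- nodes_key[[paste(h3, i3)]]
        if (is.null(to)) next
        key <- paste(min(from, to), max(from, to))
        if (key %in% seen_x) next
        seen_x <- c(seen_x, key)
        flip <- (helix_of[from] %% 2) != (helix_of[to] %% 2)
        intr <- as_built_step(pos, quat, from, to, flip = flip)
        el <- add_element(el, "crossover", from, to, intrinsic = intr,
                          stiffness = Kx, flip = flip)
      }
    }
  }
  dna_structure(nodes, el,
                metadata = list(name = doc$name %||% basename(path),
                                provenance = paste0("read_cadnano:", lattice)),
                parameters = params)
}
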