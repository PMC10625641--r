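# Parametric builders for desk-scale test structures. All builders emit
# stress-free geometries: elastic elements store the as-built relative step
# parameters as their intrinsic geometry (for ideal duplex steps these are
# exactly (0, 0, rise, 0, 0, twist)), so the built configuration is an
# equilibrium of the elastic model.

# Node block for one helix. R0 maps the local helix frame into the lab
# (column 3 = helix axis). A flipped helix runs antiparallel: node order
# still follows the helix's own 5'->3' axis, so lab positions run backwards
# and frames are rotated by pi about x.
helix_nodes <- function(origin, R0, n_bp, rise, twist_deg, flipped = FALSE) {
  tw <- twist_deg * pi / 180
  pos <- matrix(0, n_bp, 3)
  quat <- matrix(0, n_bp, 4)
  Rflip <- if (flipped) rot_x(pi) else diag(3)
  for (k in seq_len(n_bp) - 1L) {
    lev <- if (flipped) n_bp - 1L - k else k
    pos[k + 1L, ] <- origin + R0 %*% c(0, 0, lev * rise)
    quat[k + 1L, ] <- quat_from_matrix(R0 %*% Rflip %*% rot_z(k * tw))
  }
  list(pos = pos, quat = quat)
}

# Node index (1-based, within one helix) sitting at a given lab level.
level_index <- function(lev, n_bp, flipped) {
  if (flipped) n_bp - lev else lev + 1L
}

make_nodes <- function(pos, quat, sequence, params) {
  n <- nrow(pos)
  if (length(sequence) == 1 && sequence == "average") sequence <- rep("avg", n)
  mass <- base_pair_mass(sequence)
  list(pos = pos, quat = quat, mass = mass,
       inertia = node_inertia(mass), radius = rep(params$hydro_radius, n),
       sequence = sequence)
}

# Step parameters of an as-built pair, degrees (used to freeze crossover
# intrinsic geometries).
as_built_step <- function(pos, quat, i, j, flip = FALSE) {
  Ta <- matrix_from_quat(quat[i, ])
  Tb <- matrix_from_quat(quat[j, ])
  if (flip) Tb <- Tb %*% diag(c(1, -1, -1))
  p <- as.numeric(.cpp_step_parameters(Ta, pos[i, ], Tb, pos[j, ]))
  p[4:6] <- p[4:6] * 180 / pi
  p
}

#' Build a straight B-form duplex
#'
#' Node k sits at z = k * rise with its frame rotated by k * twist about the
#' helical axis; consecutive nodes are joined by step elements with intrinsic
#' geometry (0, 0, rise, 0, 0, twist) and the default step stiffness.
#'
#' @param n_bp Number of base pairs (>= 2).
#' @param sequence Watson-strand base string of length `n_bp`, or "average".
#' @param rise Intrinsic rise, nm.
#' @param twist Intrinsic twist, degrees.
#' @param params Parameter table, see [default_parameter_table()].
#' @return A [dna_structure()].
#' @export
build_duplex <- function(n_bp, sequence = "average", rise = 0.34, twist = 34.3,
                         params = default_parameter_table()) {
  if (!is.numeric(n_bp) || n_bp < 2) stop("n_bp must be at least 2")
  n_bp <- as.integer(n_bp)
  if (length(sequence) == 1 && sequence != "average")
    sequence <- strsplit(sequence, "")[[1]]
  if (length(sequence) > 1 && length(sequence) != n_bp)
    stop("sequence length must equal n_bp")
  h <- helix_nodes(c(0, 0, 0), diag(3), n_bp, rise, twist)
  nodes <- make_nodes(h$pos, h$quat, sequence, params)
  el <- empty_elements()
  K <- step_stiffness_matrix(params)
  for (k in seq_len(n_bp - 1)) {
    el <- add_element(el, "step", k, k + 1,
                      intrinsic = c(0, 0, rise, 0, 0, twist), stiffness = K)
  }
  dna_structure(nodes, el,
                metadata = list(name = sprintf("duplex_%dbp", n_bp),
                                provenance = "build_duplex"),
                parameters = params)
}

#' Build a parallel helix bundle
#'
#' Straight antiparallel helices arranged on a honeycomb or square lattice
#' (inter-helix pitch 2.5 nm), with neighboring helices joined by crossover
#' elements every `crossover_spacing` base pairs. Crossovers use the softer
#' crossover stiffness table and store the as-built relative geometry as
#' intrinsic geometry.
#'
#' @param n_helices Number of helices (>= 2).
#' @param lattice "honeycomb" or "square".
#' @param n_bp Base pairs per helix.
#' @param crossover_spacing Spacing between crossovers along a neighbor pair,
#'   in bp (>= 7).
#' @param params Parameter table.
#' @return A [dna_structure()].
#' @export
build_bundle <- function(n_helices, lattice = c("honeycomb", "square"), n_bp,
                         crossover_spacing,
                         params = default_parameter_table()) {
  lattice <- match.arg(lattice)
  if (n_helices < 2) stop("n_helices must be at least 2")
  if (crossover_spacing < 7) stop("crossover_spacing must be at least 7")
  if (crossover_spacing > n_bp)
    stop("crossover_spacing is incompatible with n_bp: no crossover fits")
  n_helices <- as.integer(n_helices); n_bp <- as.integer(n_bp)
  d <- params$helix_pitch
  hx <- vapply(seq_len(n_helices) - 1L, function(i) {
    if (lattice == "square") c(i * d, 0)
    else c(i * d * sqrt(3) / 2, (i %% 2) * d / 2)
  }, numeric(2))
  rise <- params$rise; twist <- params$twist
  pos <- NULL; quat <- NULL
  for (h in seq_len(n_helices) - 1L) {
    hh <- helix_nodes(c(hx[1, h + 1], hx[2, h + 1], 0), diag(3), n_bp, rise,
                      twist, flipped = (h %% 2 == 1))
    pos <- rbind(pos, hh$pos); quat <- rbind(quat, hh$quat)
  }
  nodes <- make_nodes(pos, quat, "average", params)
  el <- empty_elements()
  Ks <- step_stiffness_matrix(params)
  for (h in seq_len(n_helices) - 1L) {
    for (k in seq_len(n_bp - 1)) {
      i <- h * n_bp + k
      el <- add_element(el, "step", i, i + 1,
                        intrinsic = c(0, 0, rise, 0, 0, twist), stiffness = Ks)
    }
  }
  Kx <- crossover_stiffness_matrix(params)
  for (h in seq_len(n_helices - 1L) - 1L) {
    offset <- (h * 7L) %% crossover_spacing
    levs <- seq(offset, n_bp - 1L, by = crossover_spacing)
    for (lev in levs) {
      i <- h * n_bp + level_index(lev, n_bp, h %% 2 == 1)
      j <- (h + 1L) * n_bp + level_index(lev, n_bp, (h + 1L) %% 2 == 1)
      intr <- as_built_step(pos, quat, i, j, flip = TRUE)
      el <- add_element(el, "crossover", i, j, intrinsic = intr,
                        stiffness = Kx, flip = TRUE)
    }
  }
  helix_ids <- lapply(seq_len(n_helices) - 1L,
                      function(h) h * n_bp + seq_len(n_bp))
  dna_structure(nodes, el,
                metadata = list(name = sprintf("%dhb_%s_%dbp", n_helices, lattice, n_bp),
                                provenance = "build_bundle",
                                annotations = list(helices = helix_ids)),
                parameters = params)
}

#' Build a two-arm switch toy
#'
#' A reduced-scale analogue of an ion-responsive switch: two rigid multi-helix
#' arms meet head-on at a central seam. Blunt-end pairs across the seam are
#' bridged by breakable Morse stacking bonds (built at the Morse equilibrium
#' distance, i.e. the closed state), while two short single-stranded
#' connections on the innermost helix row act as the hinge that keeps the
#' arms tethered while leaving the opening rotation free. The opening angle
#' is the angle between the two fitted arm axes (0 degrees as built).
#'
#' @param arm_bp Base pairs per helix in each arm (>= 8).
#' @param n_stack_bonds Number of stacking bonds across the seam (1 to
#'   `n_helices`, hinge row last).
#' @param n_helices Helices per arm (2 to 10, a two-column square-lattice
#'   block grown from the hinge rows).
#' @param params Parameter table.
#' @return A [dna_structure()]; arm node sets and stacking element ids are in
#'   `metadata$annotations`.
#' @export
build_switch_toy <- function(arm_bp, n_stack_bonds, n_helices = 10,
                             params = default_parameter_table()) {
  if (arm_bp < 8) stop("arm_bp must be at least 8")
  if (n_helices < 2 || n_helices > 10) stop("n_helices must be between 2 and 10")
  if (n_stack_bonds < 1 || n_stack_bonds > n_helices)
    stop("n_stack_bonds exceeds available blunt-end pairs")
  arm_bp <- as.integer(arm_bp)
  d <- params$helix_pitch
  # connected two-column block grown from the hinge rows (y = 0); then
  # ordered hinge-distal first so stacking bonds fill distal rows first
  rows_all <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1), c(2, 0), c(2, 1),
                   c(3, 0), c(3, 1), c(4, 0), c(4, 1))
  rows <- rows_all[seq_len(n_helices)]
  rows <- rows[order(-vapply(rows, `[`, numeric(1), 1))]
  r0 <- params$morse$r0
  rise <- params$rise; twist <- params$twist
  RA <- rot_y(pi / 2)   # local z -> +x
  RB <- rot_y(-pi / 2)  # local z -> -x
  pos <- NULL; quat <- NULL
  seam <- list()  # per arm, per row: node id at the seam level
  nrows <- length(rows)
  for (arm in 1:2) {
    for (r in seq_len(nrows)) {
      yz <- rows[[r]] * d
      parity <- (rows[[r]][1] + rows[[r]][2]) %% 2 == 1
      org <- c(if (arm == 1) r0 / 2 else -r0 / 2, yz[1], yz[2])
      hh <- helix_nodes(org, if (arm == 1) RA else RB, arm_bp, rise, twist,
                        flipped = parity)
      base <- nrow(pos %||% matrix(0, 0, 3))
      pos <- rbind(pos, hh$pos); quat <- rbind(quat, hh$quat)
      seam[[paste(arm, r)]] <- base + level_index(0L, arm_bp, parity)
    }
  }
  nodes <- make_nodes(pos, quat, "average", params)
  el <- empty_elements()
  Ks <- step_stiffness_matrix(params)
  Kx <- crossover_stiffness_matrix(params)
  for (arm in 1:2) {
    for (r in seq_len(nrows)) {
      base <- ((arm - 1) * nrows + (r - 1)) * arm_bp
      for (k in seq_len(arm_bp - 1)) {
        el <- add_element(el, "step", base + k, base + k + 1,
                          intrinsic = c(0, 0, rise, 0, 0, twist), stiffness = Ks)
      }
    }
    # rigidify the arm: crossovers near both ends and at mid-arm of each
    # adjacent row pair
    for (r1 in seq_len(nrows - 1)) {
      for (r2 in (r1 + 1):nrows) {
        if (sum(abs(rows[[r1]] - rows[[r2]])) != 1) next
        p1 <- (rows[[r1]][1] + rows[[r1]][2]) %% 2 == 1
        p2 <- (rows[[r2]][1] + rows[[r2]][2]) %% 2 == 1
        b1 <- ((arm - 1) * nrows + (r1 - 1)) * arm_bp
        b2 <- ((arm - 1) * nrows + (r2 - 1)) * arm_bp
        for (lev in unique(c(1L, arm_bp %/% 2L, arm_bp - 2L))) {
          i <- b1 + level_index(lev, arm_bp, p1)
          j <- b2 + level_index(lev, arm_bp, p2)
          intr <- as_built_step(pos, quat, i, j, flip = TRUE)
          el <- add_element(el, "crossover", i, j, intrinsic = intr,
                            stiffness = Kx, flip = TRUE)
        }
      }
    }
  }
  # stacking bonds across the seam, hinge-distal rows first: bonds far from
  # the hinge are the ones electrostatic repulsion can lever open
  mp <- params$morse
  stack_ids <- integer(0)
  for (r in seq_len(n_stack_bonds)) {
    i <- seam[[paste(1, r)]]; j <- seam[[paste(2, r)]]
    el <- add_element(el, "stacking", i, j,
                      morse = c(mp$epsilon, mp$a, mp$r0))
    stack_ids <- c(stack_ids, length(el$kind))
  }
  # hinge: entropic-spring single-stranded connections on the two hinge rows
  k_ss <- ssdna_spring_constant(2, params)
  Kss <- matrix(0, 6, 6); Kss[1, 1] <- k_ss
  for (r in (nrows - 1):nrows) {
    i <- seam[[paste(1, r)]]; j <- seam[[paste(2, r)]]
    el <- add_element(el, "ssdna", i, j, intrinsic = c(0, 0, r0, 0, 0, 0),
                      stiffness = Kss)
  }
  # retaining scaffold loops across the two distal seam pairs: slack 10-nt
  # entropic springs. They bound the opening excursion and bias the open
  # arms back toward the closed geometry — the role the scaffold routing
  # plays in real reconfigurable designs. Softer loops open wider but close
  # slower; 10 nt re-closes a released arm within a few hundred ns
  k_loop <- ssdna_spring_constant(10, params)
  Kloop <- matrix(0, 6, 6); Kloop[1, 1] <- k_loop
  for (r in if (nrows >= 4) 1:2 else integer(0)) {
    i <- seam[[paste(1, r)]]; j <- seam[[paste(2, r)]]
    el <- add_element(el, "ssdna", i, j, intrinsic = c(0, 0, r0, 0, 0, 0),
                      stiffness = Kloop)
  }
  arm_ids <- lapply(1:2, function(a) ((a - 1) * nrows * arm_bp) + seq_len(nrows * arm_bp))
  # the coaxial blunt-end contact zone across the seam (same helix row, a
  # few base pairs either side) is the stacking interaction's domain: those
  # pairs are excluded from point-charge electrostatics, which would only
  # add spurious stiffness and hard-core encounters at sub-nm separations
  seam_edges <- NULL
  for (r in seq_len(nrows)) {
    p1 <- (rows[[r]][1] + rows[[r]][2]) %% 2 == 1
    b1 <- (r - 1) * arm_bp
    b2 <- (nrows + r - 1) * arm_bp
    ids1 <- b1 + vapply(0:2, function(l) as.integer(level_index(l, arm_bp, p1)), integer(1))
    ids2 <- b2 + vapply(0:2, function(l) as.integer(level_index(l, arm_bp, p1)), integer(1))
    seam_edges <- rbind(seam_edges, as.matrix(expand.grid(ids1, ids2)))
  }
  dna_structure(nodes, el,
                metadata = list(name = sprintf("switch_toy_%dbp_%dbonds", arm_bp, n_stack_bonds),
                                provenance = "build_switch_toy",
                                exclusion_edges = seam_edges,
                                annotations = list(arms = arm_ids,
                                                   arm_axis_ref = list(c(1, 0, 0), c(-1, 0, 0)),
                                                   arm_nodes = arm_ids,
                                                   stacking_elements = stack_ids)),
                parameters = params)
}

#' Build a planar wireframe polygon
#'
#' Triangular, square or hexagonal wireframes whose edges are two-helix (DX)
#' or six-helix (6HB) bundles and whose vertices are joined by single-stranded
#' connections. The ideal interior angle is 180 (n - 2) / n degrees.
#'
#' @param n_edges 3, 4 or 6.
#' @param edge_type "DX" (2 helices) or "6HB" (6 helices, honeycomb ring).
#' @param circumradius Circumscribed-circle radius, nm; must leave room for
#'   at least two crossover-spaced segments per edge.
#' @param crossover_spacing Crossover spacing along edges, bp.
#' @param params Parameter table.
#' @return A [dna_structure()] with edge node sets in `metadata$annotations`.
#' @export
build_wireframe_polygon <- function(n_edges, edge_type = c("DX", "6HB"),
                                    circumradius,
                                    crossover_spacing = 21,
                                    params = default_parameter_table()) {
  edge_type <- match.arg(edge_type)
  if (!n_edges %in% c(3, 4, 6)) stop("n_edges must be 3, 4 or 6")
  rise <- params$rise; twist <- params$twist; d <- params$helix_pitch
  vertex_gap <- 1.5 # nm kept free at each end for the vertex connection
  edge_len <- 2 * circumradius * sin(pi / n_edges) - 2 * vertex_gap
  n_bp <- floor(edge_len / rise)
  if (n_bp < 2 * crossover_spacing)
    stop("geometric infeasibility: circumradius too small for ",
         n_edges, " edges with >= 2 crossover-spaced segments")
  n_h <- if (edge_type == "DX") 2L else 6L
  # helix offsets in the plane perpendicular to the edge axis
  offs <- if (edge_type == "DX") {
    list(c(0, 0), c(d, 0))
  } else {
    lapply(0:5, function(k) d * c(cos(pi / 3 * k), sin(pi / 3 * k)))
  }
  verts <- vapply(seq_len(n_edges) - 1L, function(k) {
    th <- 2 * pi * k / n_edges
    circumradius * c(cos(th), sin(th), 0)
  }, numeric(3))
  pos <- NULL; quat <- NULL
  edge_ids <- list(); edge_ends <- list()
  for (e in seq_len(n_edges)) {
    v1 <- verts[, e]; v2 <- verts[, (e %% n_edges) + 1]
    ax <- (v2 - v1) / sqrt(sum((v2 - v1)^2))
    inplane <- c(-ax[2], ax[1], 0)           # perpendicular, in plane
    Redge <- cbind(inplane, c(0, 0, 1), ax)  # columns x, y, z(axis)
    start <- v1 + ax * vertex_gap
    base0 <- nrow(pos %||% matrix(0, 0, 3))
    for (h in seq_len(n_h) - 1L) {
      org <- start + Redge %*% c(offs[[h + 1]][1], offs[[h + 1]][2], 0)
      hh <- helix_nodes(as.numeric(org), Redge, n_bp, rise, twist,
                        flipped = (h %% 2 == 1))
      pos <- rbind(pos, hh$pos); quat <- rbind(quat, hh$quat)
    }
    edge_ids[[e]] <- base0 + seq_len(n_h * n_bp)
    edge_ends[[e]] <- list(
      start = base0 + vapply(seq_len(n_h) - 1L, function(h)
        as.integer(h * n_bp + level_index(0L, n_bp, h %% 2 == 1)), integer(1)),
      end = base0 + vapply(seq_len(n_h) - 1L, function(h)
        as.integer(h * n_bp + level_index(n_bp - 1L, n_bp, h %% 2 == 1)), integer(1)))
  }
  nodes <- make_nodes(pos, quat, "average", params)
  el <- empty_elements()
  Ks <- step_stiffness_matrix(params)
  Kx <- crossover_stiffness_matrix(params)
  for (e in seq_len(n_edges)) {
    base0 <- edge_ids[[e]][1] - 1L
    for (h in seq_len(n_h) - 1L) {
      for (k in seq_len(n_bp - 1)) {
        i <- base0 + h * n_bp + k
        el <- add_element(el, "step", i, i + 1,
                          intrinsic = c(0, 0, rise, 0, 0, twist), stiffness = Ks)
      }
    }
    for (h in seq_len(n_h - 1L) - 1L) {
      offset <- (h * 7L) %% crossover_spacing
      for (lev in seq(offset, n_bp - 1L, by = crossover_spacing)) {
        i <- base0 + h * n_bp + level_index(lev, n_bp, h %% 2 == 1)
        j <- base0 + (h + 1L) * n_bp + level_index(lev, n_bp, (h + 1L) %% 2 == 1)
        intr <- as_built_step(pos, quat, i, j, flip = TRUE)
        el <- add_element(el, "crossover", i, j, intrinsic = intr,
                          stiffness = Kx, flip = TRUE)
      }
    }
  }
  # vertex connections: ssDNA springs between matching helix ends
  n_nt <- max(2, round(2 * vertex_gap / params$ss_contour_per_nt))
  k_ss <- ssdna_spring_constant(n_nt, params)
  Kss <- matrix(0, 6, 6); Kss[1, 1] <- k_ss
  for (e in seq_len(n_edges)) {
    e2 <- (e %% n_edges) + 1
    for (h in seq_len(n_h)) {
      i <- edge_ends[[e]]$end[h]; j <- edge_ends[[e2]]$start[h]
      L0 <- sqrt(sum((pos[j, ] - pos[i, ])^2))
      el <- add_element(el, "ssdna", i, j, intrinsic = c(0, 0, L0, 0, 0, 0),
                        stiffness = Kss)
    }
  }
  dna_structure(nodes, el,
                metadata = list(name = sprintf("wireframe_%dgon_%s", n_edges, edge_type),
                                provenance = "build_wireframe_polygon",
                                annotations = list(edges = edge_ids)),
                parameters = params)
}
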