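STRUCTURE_SCHEMA_VERSION <- "1.0"

#' Write a structure to a JSON file
#'
#' Versioned JSON schema holding nodes (position, quaternion, mass, inertia,
#' radius, sequence), elements (kind, node pair, intrinsic geometry,
#' stiffness, Morse parameters, frame-flip convention), electrostatic
#' exclusions, the parameter table and metadata. The round trip through
#' [read_structure()] is lossless to full double precision.
#'
#' @param structure A `dna_structure`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_structure <- function(structure, path) {
  el <- structure$elements
  m <- length(el$kind)
  doc <- list(
    schema = "dnadyn_structure",
    schema_version = STRUCTURE_SCHEMA_VERSION,
    metadata = structure$metadata,
    parameters = structure$parameters,
    nodes = list(
      pos = structure$nodes$pos, quat = structure$nodes$quat,
      mass = structure$nodes$mass, inertia = structure$nodes$inertia,
      radius = structure$nodes$radius, sequence = structure$nodes$sequence),
    elements = list(
      kind = el$kind, nodes = el$nodes, intrinsic = el$intrinsic,
      stiffness = lapply(seq_len(m), function(e) el$stiffness[, , e]),
      morse = el$morse, flip = el$flip),
    electro_exclusions = structure$electro_exclusions)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = FALSE, na = "null")
  invisible(path)
}

#' Read a structure from a JSON file
#'
#' @param path Path to a file written by [write_structure()].
#' @return A `dna_structure`; schema violations raise errors naming the
#'   offending record.
#' @export
read_structure <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "dnadyn_structure"))
    stop("not a dnadyn structure file: ", path)
  if (!identical(doc$schema_version, STRUCTURE_SCHEMA_VERSION))
    stop("unsupported structure schema version '", doc$schema_version,
         "' (supported: ", STRUCTURE_SCHEMA_VERSION, ")")
  nd <- doc$nodes
  nodes <- list(pos = as.matrix(nd$pos), quat = as.matrix(nd$quat),
                mass = as.numeric(nd$mass),
                inertia = as.matrix(nd$inertia),
                radius = as.numeric(nd$radius),
                sequence = as.character(nd$sequence))
  eld <- doc$elements
  m <- length(eld$kind)
  stiff <- array(0, c(6, 6, m))
  for (e in seq_len(m)) {
    K <- eld$stiffness
    stiff[, , e] <- if (is.list(K)) as.matrix(K[[e]]) else matrix(K[e, , ], 6, 6)
  }
  morse <- if (m > 0) matrix(as.numeric(as.matrix(eld$morse)), ncol = 3)
           else matrix(numeric(), 0, 3)
  intr <- if (m > 0) matrix(as.numeric(as.matrix(eld$intrinsic)), ncol = 6)
          else matrix(numeric(), 0, 6)
  elements <- list(kind = as.character(eld$kind),
                   nodes = matrix(as.integer(as.matrix(eld$nodes)), ncol = 2),
                   intrinsic = intr,
                   stiffness = stiff, morse = morse,
                   flip = as.logical(eld$flip))
  n <- nrow(nodes$pos)
  bad <- which(elements$nodes < 1 | elements$nodes > n, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("element ", bad[1, 1], " references missing node ",
         elements$nodes[bad[1, 1], bad[1, 2]])
  params <- doc$parameters
  x <- dna_structure(nodes, elements, metadata = doc$metadata,
                     parameters = params)
  x
}
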