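# Connectivity-based data filtration: perceive bonds from Cartesian
# geometries, compare against the intended topology, and apply the
# discard/flag rules used when curating optimized structures (a molecule is
# dropped if any of its optimization records rearranged; records with
# imaginary frequencies in an ionic state are kept but flagged).

# single-bond covalent radii (angstrom), Cordero et al. consensus values
.covalent_radii <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66)

#' Perceive bonds from Cartesian coordinates
#'
#' Two atoms are bonded when their distance does not exceed
#' `scale * (r_cov(i) + r_cov(j))` with standard covalent radii and
#' `scale = 1.2`.  Atom pairs closer than 0.4 angstrom indicate a broken
#' geometry and raise an error.
#'
#' @param coords data frame with columns `element`, `x`, `y`, `z` (angstrom).
#' @param scale covalent-radius multiplier.
#' @return A two-column matrix of bonded atom-index pairs (row < column).
#' @export
perceive_bonds <- function(coords, scale = 1.2) {
  stopifnot(is.data.frame(coords),
            all(c("element", "x", "y", "z") %in% names(coords)),
            nrow(coords) >= 2)
  unknown <- setdiff(unique(coords$element), names(.covalent_radii))
  if (length(unknown))
    stop("no covalent radius for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  d <- as.matrix(stats::dist(coords[, c("x", "y", "z")]))
  diag(d) <- Inf
  if (any(d < 0.4))
    stop("overlapping atoms: minimum interatomic distance below 0.4 angstrom",
         call. = FALSE)
  r <- .covalent_radii[coords$element]
  cutoff <- scale * outer(r, r, `+`)
  idx <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  bonds <- cbind(idx[, 1], idx[, 2])
  dimnames(bonds) <- NULL
  bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
}

# explicit-hydrogen igraph from a mol_graph (H vertices appended after the
# heavy atoms, each bonded to its host)
.reference_igraph <- function(graph, elements = graph$element) {
  hosts <- which(graph$h_count == 1L)
  n <- graph$n_atoms
  hbonds <- cbind(hosts, n + seq_along(hosts))
  g <- igraph::graph_from_edgelist(rbind(graph$bonds, hbonds),
                                   directed = FALSE)
  igraph::V(g)$element <- c(elements, rep("H", length(hosts)))
  g
}

.observed_igraph <- function(coords, bonds) {
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  g <- igraph::add_edges(g, t(bonds))
  igraph::V(g)$element <- coords$element
  g
}

#' Has a geometry rearranged relative to its intended topology?
#'
#' Compares the perceived connectivity against the reference molecular graph
#' (explicit hydrogens, element-respecting) by graph isomorphism, the same
#' decision boundary as comparing standard InChI connectivity layers for
#' these frameworks.
#'
#' @param reference a `mol_graph` (its implicit hydrogens are expanded).
#' @param coords coordinates of the observed structure (including hydrogens).
#' @param bonds observed bond matrix, e.g. from [perceive_bonds()];
#'   perceived from `coords` when omitted.
#' @param elements optional element vector overriding the reference's (to
#'   compare against a substituted isomer without rebuilding the graph).
#' @return `TRUE` when the observed connectivity is *not* isomorphic to the
#'   reference.
#' @export
detect_rearrangement <- function(reference, coords, bonds = NULL,
                                 elements = reference$element) {
  stopifnot(inherits(reference, "mol_graph"))
  if (is.null(bonds)) bonds <- perceive_bonds(coords)
  ref <- .reference_igraph(reference, elements)
  obs <- .observed_igraph(coords, bonds)
  if (igraph::vcount(ref) != igraph::vcount(obs)) return(TRUE)
  ref_el <- sort(igraph::V(ref)$element)
  obs_el <- sort(igraph::V(obs)$element)
  if (!identical(ref_el, obs_el))
    stop("atom multisets differ between reference and observed structure",
         call. = FALSE)
  lv <- sort(unique(ref_el))
  !igraph::is_isomorphic_to(
    ref, obs, method = "vf2",
    vertex.color1 = match(igraph::V(ref)$element, lv),
    vertex.color2 = match(igraph::V(obs)$element, lv))
}

#' Construct a geometry record
#'
#' One optimization result for one molecule: geometry, charge state, method
#' and the imaginary-frequency flag produced by the frequency calculation
#' (consumed as an input here; computing frequencies is out of scope).
#'
#' @param molecule_id molecule identifier shared by all records of a molecule.
#' @param coords data frame with `element`, `x`, `y`, `z`.
#' @param charge_state one of `"neutral"`, `"cation"`, `"anion"`.
#' @param method one of `"dft"`, `"xtb"`.
#' @param imaginary_freq logical flag.
#' @return An object of class `geometry_record`.
#' @export
geometry_record <- function(molecule_id, coords,
                            charge_state = c("neutral", "cation", "anion"),
                            method = c("dft", "xtb"),
                            imaginary_freq = FALSE) {
  charge_state <- match.arg(charge_state)
  method <- match.arg(method)
  stopifnot(is.data.frame(coords),
            all(c("element", "x", "y", "z") %in% names(coords)))
  structure(list(molecule_id = molecule_id, charge_state = charge_state,
                 method = method, coords = coords,
                 imaginary_freq = isTRUE(imaginary_freq)),
            class = "geometry_record")
}

#' Apply the filtration rule to grouped optimization records
#'
#' A molecule is *discarded* when any of its (up to six: two methods times
#' three charge states) records rearranged relative to its reference
#' topology; it is *flagged* (kept, but to be excluded from adiabatic
#' ionization-potential / electron-affinity analyses) when any ionic record
#' has an imaginary frequency; otherwise it is kept clean.  Molecules with
#' missing records are evaluated on the available ones, with a warning.
#'
#' @param records list of [geometry_record()] objects.
#' @param references named list of `mol_graph` references, indexed by
#'   `molecule_id`.
#' @param elements optional named list of element vectors (per molecule) for
#'   substituted isomers.
#' @return A list with character vectors `kept`, `discarded`, `flagged`
#'   (flagged is a subset of kept) and a `log` data frame with one row per
#'   molecule-record describing the decision.
#' @export
apply_filtration <- function(records, references, elements = NULL) {
  stopifnot(is.list(records),
            all(vapply(records, inherits, logical(1), "geometry_record")))
  ids <- vapply(records, `[[`, character(1), "molecule_id")
  kept <- character(); discarded <- character(); flagged <- character()
  log <- list()
  for (id in unique(ids)) {
    recs <- records[ids == id]
    if (length(recs) < 6L)
      warning(sprintf("molecule %s has %d of 6 records; evaluating available ones",
                      id, length(recs)), call. = FALSE)
    ref <- references[[id]]
    if (is.null(ref))
      stop("no reference topology for molecule ", id, call. = FALSE)
    el <- if (is.null(elements)) ref$element else elements[[id]]
    rearranged <- vapply(recs, function(r)
      detect_rearrangement(ref, r$coords, elements = el), logical(1))
    imag_ionic <- vapply(recs, function(r)
      r$imaginary_freq && r$charge_state != "neutral", logical(1))
    for (k in seq_along(recs)) {
      log[[length(log) + 1L]] <- data.frame(
        molecule_id = id,
        method = recs[[k]]$method,
        charge_state = recs[[k]]$charge_state,
        rearranged = rearranged[k],
        imaginary_ionic = imag_ionic[k])
    }
    if (any(rearranged)) {
      discarded <- c(discarded, id)
    } else {
      kept <- c(kept, id)
      if (any(imag_ionic)) flagged <- c(flagged, id)
    }
  }
  list(kept = kept, discarded = discarded, flagged = flagged,
       log = do.call(rbind, log))
}

#' Write geometry records as a multi-structure XYZ file
#'
#' Standard XYZ blocks; the comment line carries the record metadata as
#' `id=<id> charge=<state> method=<m> imag=<0|1>`.
#'
#' @param records list of [geometry_record()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(records, path) {
  if (inherits(records, "geometry_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(as.character(nrow(r$coords)), con)
    writeLines(sprintf("id=%s charge=%s method=%s imag=%d",
                       r$molecule_id, r$charge_state, r$method,
                       as.integer(r$imaginary_freq)), con)
    writeLines(sprintf("%-2s %14.8f %14.8f %14.8f", r$coords$element,
                       r$coords$x, r$coords$y, r$coords$z), con)
  }
  invisible(path)
}

#' Read a multi-structure XYZ file written by [write_xyz()]
#'
#' Comment lines without the metadata tags yield records with id
#' `"structure_<k>"`, neutral charge, dft method and no imaginary flag.
#'
#' @param path file path.
#' @return A list of [geometry_record()] objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- as.integer(trimws(lines[i]))
    if (is.na(nat)) stop("malformed XYZ: expected atom count at line ", i,
                         call. = FALSE)
    k <- k + 1L
    comment <- lines[i + 1L]
    atoms <- lines[(i + 2L):(i + 1L + nat)]
    parts <- strsplit(trimws(atoms), "[[:space:]]+")
    coords <- data.frame(
      element = vapply(parts, `[`, character(1), 1),
      x = as.numeric(vapply(parts, `[`, character(1), 2)),
      y = as.numeric(vapply(parts, `[`, character(1), 3)),
      z = as.numeric(vapply(parts, `[`, character(1), 4)))
    meta <- function(key, default) {
      m <- regmatches(comment, regexpr(paste0(key, "=[^ ]+"), comment))
      if (length(m)) sub(paste0(key, "="), "", m) else default
    }
    out[[k]] <- geometry_record(
      molecule_id = meta("id", sprintf("structure_%d", k)),
      coords = coords,
      charge_state = meta("charge", "neutral"),
      method = meta("method", "dft"),
      imaginary_freq = meta("imag", "0") == "1")
    i <- i + 2L + nat
  }
  out
}
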