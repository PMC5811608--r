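#' Atomic structure container with prothrombin domain labels
#'
#' A light S3 wrapper around an atom table: element, atom name, residue
#' number (prothrombin 1-579 numbering), chain, coordinates in Angstrom and
#' a van der Waals radius per atom. Domain labels follow the modular
#' architecture of prothrombin: Gla 1-46, kringle-1 65-143, kringle-2
#' 170-248, protease 285-579.
#'
#' @param atoms data.frame with columns `element`, `name`, `resno`, `chain`,
#'   `x`, `y`, `z` and optionally `radius` (filled from [vdw_radius()] when
#'   absent).
#' @param domains Named list of residue ranges (2-vectors).
#' @return Object of class `structure_model`.
#' @export
structure_model <- function(atoms, domains = prothrombin_domains()) {
  need <- c("element", "name", "resno", "chain", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop_config("atom table must have columns ",
                paste(need, collapse = ", "))
  if (!nrow(atoms)) stop_config("empty structure")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop_config("non-finite coordinates")
  if (is.null(atoms$radius)) atoms$radius <- vdw_radius(atoms$element)
  if (any(atoms$radius <= 0)) stop_config("van der Waals radii must be > 0")
  structure(list(atoms = atoms, domains = domains),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resno)), "residues\n")
  invisible(x)
}

#' Standard domain boundaries of human prothrombin (1-579 numbering).
#' @return Named list of residue ranges.
#' @export
prothrombin_domains <- function() {
  list(gla = c(1, 46), kringle1 = c(65, 143),
       kringle2 = c(170, 248), protease = c(285, 579))
}

#' Van der Waals radii by element (Angstrom; Bondi-style values).
#' @param element Character vector of element symbols.
#' @return Numeric radii; unknown elements get the carbon radius.
#' @export
vdw_radius <- function(element) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
           P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
           I = 1.98, CA = 2.31, ZN = 1.39, MG = 1.73, "NA" = 2.27)
  r <- tab[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read a protein structure from PDB/mmCIF
#'
#' Loads heavy atoms (hydrogens, waters and hetero groups excluded by
#' default), keeps the highest-occupancy alternate location per atom, and
#' optionally renumbers residues into the prothrombin 1-579 scheme via an
#' explicit map; no renumbering is ever guessed silently.
#'
#' @param path PDB (or mmCIF, as supported by bio3d) file path.
#' @param renumber Optional data.frame (`auth`, `target`) mapping deposited
#'   residue numbers to the 1-579 numbering; identity by default.
#' @param keep_hetero Keep HETATM records (default FALSE).
#' @param chain Optional chain filter.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, renumber = NULL, keep_hetero = FALSE,
                           chain = NULL) {
  if (!file.exists(path)) stop_config("no such file: ", path)
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE)
  at <- pdb$atom
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[at$resid != "HOH", , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  at <- at[is.na(at$elesy) | toupper(at$elesy) != "H", , drop = FALSE]
  if (!nrow(at)) stop_config("no atoms left after filtering: ", path)
  # highest-occupancy altloc per (chain, resno, atom name)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(key, -occ)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | !nzchar(elem)))
    elem <- substr(gsub("[0-9]", "", at$elety), 1, 1)
  resno <- at$resno
  if (!is.null(renumber)) {
    stopifnot(all(c("auth", "target") %in% names(renumber)))
    idx <- match(resno, renumber$auth)
    if (anyNA(idx)) stop_config("renumbering map misses residues: ",
                                paste(unique(resno[is.na(idx)])[1:5],
                                      collapse = ", "))
    resno <- renumber$target[idx]
  }
  structure_model(data.frame(element = toupper(elem), name = at$elety,
                             resno = resno, chain = at$chain,
                             x = at$x, y = at$y, z = at$z,
                             stringsAsFactors = FALSE))
}

#' Write a structure model as a PDB file
#' @param model A [structure_model()].
#' @param path Output path.
#' @export
write_structure_pdb <- function(model, path) {
  a <- model$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(as.matrix(
                     a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = rep("ALA", nrow(a)),
                   eleno = seq_len(nrow(a)), elety = a$name,
                   chain = a$chain, elesy = a$element)
  invisible(path)
}

#' Fetch a PDB entry from the RCSB (requires network access)
#'
#' Thin download helper for deposited coordinates such as the closed-form
#' prothrombin structures 6BJR/6C2W. Fails with a clear message when no
#' network is available.
#'
#' @param id 4-character PDB id.
#' @param dest_dir Download directory.
#' @return Path to the downloaded PDB file.
#' @export
fetch_pdb <- function(id, dest_dir = tempdir()) {
  dest <- file.path(dest_dir, paste0(toupper(id), ".pdb"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download PDB entry ", id,
         " (no network access?); supply a local file instead", call. = FALSE)
  }
  dest
}

#' Generate a two-domain toy structure with exact labelled-site distances
#'
#' Builds two compact pseudo-atom clusters ("domains") of carbon beads with
#' one labelled site per domain. The site atoms sit on the facing surfaces
#' of the two domains (real labelling sites are solvent-exposed, so dye
#' clouds computed at them have free space), at (0, 0, 0) and
#' (`separation`, 0, 0): the inter-site distance equals `separation`
#' exactly by construction — a controllable fixture for FRET prediction
#' and SAXS model discrimination (e.g. a 54 A dumbbell mimicking the
#' kringle-1 to kringle-2 linker span).
#'
#' @param n_atoms_per_domain Beads per domain (>= 1).
#' @param domain_radius Radius of each cluster, Angstrom.
#' @param separation Site-site distance, Angstrom (>= 0).
#' @param seed Seed; the structure is deterministic given it.
#' @param resno_offset Residue numbers start here + 1 for domain A; domain B
#'   continues after A.
#' @return A [structure_model()] whose attribute `sites` holds the two
#'   labelled atom indices (one per domain; the first residue of each).
#' @export
generate_toy_structure <- function(n_atoms_per_domain = 40,
                                   domain_radius = 10,
                                   separation = 50,
                                   seed = 1L,
                                   resno_offset = 0L) {
  if (separation < 0) stop_config("`separation` must be >= 0")
  stopifnot(n_atoms_per_domain >= 1)
  with_seed(seed, {
    cluster <- function(site, center, n, resno0) {
      # site bead exactly at `site`; the rest uniform in the ball
      u <- stats::runif(3 * (n - 1))
      dim(u) <- c(n - 1, 3)
      pts <- (u - 0.5) * 2
      keep_r <- domain_radius * stats::runif(n - 1)^(1 / 3)
      nrm <- sqrt(rowSums(pts^2)); nrm[nrm == 0] <- 1
      pts <- pts / nrm * keep_r
      xyz <- rbind(site, sweep(pts, 2, center, "+"))
      data.frame(element = "C", name = "CA",
                 resno = resno0 + seq_len(n), chain = "A",
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE)
    }
    # domain bodies sit behind their sites, away from the partner domain
    a <- cluster(c(0, 0, 0), c(-domain_radius, 0, 0),
                 n_atoms_per_domain, resno_offset)
    b <- cluster(c(separation, 0, 0), c(separation + domain_radius, 0, 0),
                 n_atoms_per_domain, resno_offset + n_atoms_per_domain)
    m <- structure_model(rbind(a, b), domains = list(
      domA = c(resno_offset + 1, resno_offset + n_atoms_per_domain),
      domB = c(resno_offset + n_atoms_per_domain + 1,
               resno_offset + 2 * n_atoms_per_domain)))
    attr(m, "sites") <- c(1L, n_atoms_per_domain + 1L)
    m
  })
}

#' Distance between two C-alpha atoms
#'
#' Euclidean distance in Angstrom between the CA atoms of two residues,
#' e.g. the ~54 A span between Cys143 (kringle-1) and Cys170 (kringle-2)
#' that sets the minimum linker length compatible with the closed form.
#'
#' @param model A [structure_model()].
#' @param res_a,res_b Residue numbers.
#' @param atom Atom name (default `"CA"`).
#' @return Distance in Angstrom.
#' @export
ca_distance <- function(model, res_a, res_b, atom = "CA") {
  get_xyz <- function(r) {
    i <- which(model$atoms$resno == r & model$atoms$name == atom)
    if (!length(i))
      stop("residue ", r, " has no atom ", atom, call. = FALSE)
    unlist(model$atoms[i[1], c("x", "y", "z")], use.names = FALSE)
  }
  sqrt(sum((get_xyz(res_a) - get_xyz(res_b))^2))
}

# xyz matrix helper
atom_xyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])
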