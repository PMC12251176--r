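#' Construct a structure model
#'
#' One ensemble member: atomic coordinates plus a per-atom confidence value
#' (the AlphaFold convention stores per-residue pLDDT, 0-100, in the B-factor
#' column). The per-model score `mean_confidence` is the mean over residues of
#' the confidence of each residue's first atom.
#'
#' @param model_id identifier string.
#' @param atoms tibble with columns `element`, `atom_name`, `res_name`,
#'   `res_id` (integer), `chain`, `x`, `y`, `z` (Angstrom), `confidence`.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(model_id, atoms) {
  atoms <- tibble::as_tibble(atoms)
  req <- c("element", "atom_name", "res_name", "res_id", "chain",
           "x", "y", "z", "confidence")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(atoms) == 0L) stop("empty model: no atoms", call. = FALSE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates in model ", model_id, call. = FALSE)
  mc <- mean_residue_confidence(atoms)
  structure(list(model_id = as.character(model_id), atoms = atoms,
                 mean_confidence = mc),
            class = "structure_model")
}

mean_residue_confidence <- function(atoms) {
  first <- !duplicated(paste(atoms$chain, atoms$res_id))
  mean(atoms$confidence[first])
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues, mean confidence %.2f\n",
              x$model_id, nrow(x$atoms),
              sum(!duplicated(paste(x$atoms$chain, x$atoms$res_id))),
              x$mean_confidence))
  invisible(x)
}

model_xyz <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

atom_key <- function(atoms) paste(atoms$chain, atoms$res_id, atoms$atom_name, sep = "|")

#' Construct an ensemble of structure models
#'
#' @param models list of [structure_model()] objects.
#' @param provenance named list of free-form metadata.
#' @return an object of class `structure_ensemble`.
#' @export
structure_ensemble <- function(models, provenance = list()) {
  stopifnot(is.list(models), all(vapply(models, inherits, TRUE, "structure_model")))
  if (length(models) == 0L) stop("empty ensemble", call. = FALSE)
  structure(list(models = models, provenance = provenance),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("<structure_ensemble> %d models, %d atoms each\n",
              length(x$models), nrow(x$models[[1]]$atoms)))
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$models)

#' Per-model summary of an ensemble
#'
#' @param x a [structure_ensemble()].
#' @param ... unused.
#' @return tibble with one row per model: `model_id`, `n_atoms`,
#'   `mean_confidence`.
#' @importFrom generics tidy
#' @export
tidy.structure_ensemble <- function(x, ...) {
  tibble::tibble(
    model_id = vapply(x$models, `[[`, "", "model_id"),
    n_atoms = vapply(x$models, function(m) nrow(m$atoms), 0L),
    mean_confidence = vapply(x$models, `[[`, 0, "mean_confidence"))
}

guess_element <- function(atom_name) {
  nm <- gsub("[0-9' ]", "", toupper(atom_name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA", "SE"), two,
         substr(nm, 1, 1))
}

bio3d_to_atoms <- function(atom_df, xyz_row) {
  n <- nrow(atom_df)
  ele <- atom_df$elesy
  if (is.null(ele)) ele <- rep(NA_character_, n)
  ele <- trimws(ele)
  need <- is.na(ele) | !nzchar(ele)
  ele[need] <- guess_element(atom_df$elety[need])
  ch <- atom_df$chain
  ch[is.na(ch) | !nzchar(ch)] <- "A"
  tibble::tibble(
    element = toupper(ele),
    atom_name = trimws(atom_df$elety),
    res_name = trimws(atom_df$resid),
    res_id = as.integer(atom_df$resno),
    chain = ch,
    x = xyz_row[seq(1, 3 * n, 3)],
    y = xyz_row[seq(2, 3 * n, 3)],
    z = xyz_row[seq(3, 3 * n, 3)],
    confidence = as.numeric(atom_df$b))
}

# highest occupancy wins; ties broken toward altloc "A", then file order;
# returns row indices to keep
altloc_keep_idx <- function(atom_df) {
  n <- nrow(atom_df)
  alt <- atom_df$alt
  if (is.null(alt)) return(seq_len(n))
  alt[is.na(alt)] <- ""
  occ <- atom_df$o
  if (is.null(occ)) occ <- rep(1, n)
  occ[is.na(occ)] <- 1
  key <- paste(atom_df$chain, atom_df$resno, atom_df$elety)
  ord <- order(key, -occ, alt != "A" & nzchar(alt), seq_len(n))
  sort(ord[!duplicated(key[ord])])
}

#' Read a structure file into one or more structure models
#'
#' Reads PDB or mmCIF (chosen by extension). Per-atom confidence is taken from
#' the B-factor / temperature-factor column, following the AlphaFold
#' convention of storing pLDDT there. Multi-MODEL PDB files yield one
#' `structure_model` per MODEL record.
#'
#' @param path path to a `.pdb`, `.ent`, `.cif` or `.mmcif` file.
#' @param model_id id for the model; defaults to the file name without
#'   extension (suffixed `_1`, `_2`, ... for multi-model files).
#' @return a [structure_model()], or a list of them for multi-model files.
#' @export
read_structure <- function(path, model_id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("cannot read structure file: ", path, call. = FALSE)
  is_cif <- grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)
  parsed <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse structure file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(parsed$atom) || nrow(parsed$atom) == 0L)
    stop("no atoms in ", path, call. = FALSE)
  keep_idx <- altloc_keep_idx(parsed$atom)
  atom_df <- parsed$atom[keep_idx, , drop = FALSE]
  xyz <- parsed$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  cols <- as.vector(rbind(3 * keep_idx - 2, 3 * keep_idx - 1, 3 * keep_idx))
  models <- lapply(seq_len(n_models), function(k) {
    atoms <- bio3d_to_atoms(atom_df, xyz[k, cols])
    if (all(atoms$confidence == 0))
      warning("all B-factors zero in ", path, "; confidence is 0", call. = FALSE)
    id <- if (n_models > 1L) paste0(model_id, "_", k) else model_id
    structure_model(id, atoms)
  })
  if (n_models == 1L) models[[1]] else models
}

#' Read a directory of structure files as an ensemble
#'
#' Files are read in lexicographic filename order, then reduced to the common
#' atom set: the intersection of `(chain, residue index, atom name)` across
#' all models, so downstream superposition and averaging are well defined.
#'
#' @param dir directory path.
#' @param pattern filename glob (default `"*.pdb"`).
#' @param provenance optional named list of metadata to attach.
#' @return a [structure_ensemble()].
#' @export
read_ensemble <- function(dir, pattern = "*.pdb", provenance = list()) {
  files <- sort(list.files(dir, pattern = utils::glob2rx(pattern), full.names = TRUE))
  if (length(files) == 0L)
    stop("no files matching '", pattern, "' in ", dir, call. = FALSE)
  models <- purrr::flatten(purrr::map(files, function(f) {
    m <- read_structure(f)
    if (inherits(m, "structure_model")) list(m) else m
  }))
  provenance$source_dir <- dir
  provenance$n_files <- length(files)
  structure_ensemble(reduce_common_atoms(models), provenance)
}

#' Reduce models to their shared atoms
#'
#' Keeps only atoms present in every model, identified by
#' `(chain, residue index, atom name)`, and puts all models in the same
#' canonical atom order. Idempotent, and independent of model order.
#'
#' @param models list of [structure_model()] objects.
#' @return list of models with identical atom counts and ordering.
#' @export
reduce_common_atoms <- function(models) {
  keys <- lapply(models, function(m) atom_key(m$atoms))
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0L)
    stop("no atoms shared by all models: inconsistent topologies", call. = FALSE)
  lapply(models, function(m) {
    idx <- match(shared, atom_key(m$atoms))
    atoms <- m$atoms[idx, , drop = FALSE]
    ord <- order(atoms$chain, atoms$res_id, atoms$atom_name)
    structure_model(m$model_id, atoms[ord, , drop = FALSE])
  })
}

#' Write a structure model as a PDB file
#'
#' Confidence is written to the B-factor column (AlphaFold convention), so
#' files written here are valid inputs to [read_structure()].
#'
#' @param model a [structure_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  name_fmt <- ifelse(nchar(a$atom_name) < 4L,
                     sprintf(" %-3s", a$atom_name),
                     sprintf("%-4s", a$atom_name))
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_fmt, substr(a$res_name, 1, 3), substr(a$chain, 1, 1),
    a$res_id, a$x, a$y, a$z, 1.0, a$confidence, substr(a$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
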