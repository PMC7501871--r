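# Residue-pair backbone distance series across per-frame atomic models.
# Per movie frame, several starting models are fitted independently; the
# reported distance is their mean and the error bar the full scatter
# (minimum to maximum), not a standard deviation.

#' Read an atomic model from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d) and resolves alternate
#' locations: for each (chain, residue, atom name) the highest-occupancy
#' altloc is kept, ties going to altloc "A". Duplicate atoms remaining
#' after altloc resolution are an error.
#'
#' @param path PDB file path.
#' @param source Optional label (starting-model id / frame index).
#' @return Object of class `atomic_model`: data.frame `atoms` with
#'   `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`, and `source`.
#' @export
read_model <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0) stop("no ATOM records in ", path)
  alt <- a$alt
  alt[is.na(alt) | alt == ""] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  key <- paste(a$chain, a$resno, a$elety, sep = "|")
  keep <- logical(nrow(a))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1) { keep[idx] <- TRUE; next }
    best <- idx[occ[idx] == max(occ[idx])]
    if (length(best) > 1) {
      ba <- best[alt[best] == "A"]
      best <- if (length(ba) > 0) ba[1] else best[1]
    }
    keep[best] <- TRUE
  }
  atoms <- a[keep, c("chain", "resno", "resid", "elety", "x", "y", "z")]
  dup <- duplicated(paste(atoms$chain, atoms$resno, atoms$elety))
  if (any(dup)) {
    d <- atoms[which(dup)[1], ]
    stop(sprintf("duplicate atom %s %s/%d in %s",
                 d$elety, d$chain, d$resno, path))
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in ", path)
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source = source), class = "atomic_model")
}

resolve_atom <- function(model, sel) {
  atom <- if (length(sel) >= 3 && !is.na(sel[3])) sel[3] else "CA"
  hit <- which(model$atoms$chain == sel[1] &
                 model$atoms$resno == as.integer(sel[2]) &
                 model$atoms$elety == atom)
  if (length(hit) != 1)
    stop(sprintf("selection %s/%s/%s resolves to %d atoms",
                 sel[1], sel[2], atom, length(hit)))
  unlist(model$atoms[hit, c("x", "y", "z")])
}

#' Distance between two backbone atoms
#'
#' Euclidean distance in Angstrom between two atom selections; the
#' default atom is the alpha-carbon (CA).
#'
#' @param model An [read_model()] result.
#' @param selA,selB Selections `c(chain, resno)` or `c(chain, resno,
#'   atom)`.
#' @return Distance in Angstrom.
#' @export
backbone_distance <- function(model, selA, selB) {
  a <- resolve_atom(model, as.character(selA))
  b <- resolve_atom(model, as.character(selB))
  sqrt(sum((a - b)^2))
}

#' Distance series over frames with multi-model scatter
#'
#' For each frame, the distance is computed in every starting model fitted
#' to that frame; the series reports the per-frame mean and the full
#' scatter (min, max) across starting models. A model missing the
#' selection is skipped with a warning (the frame mean uses the remaining
#' models); a frame in which no model resolves is an error.
#'
#' @param models List over frames; each element a list of `atomic_model`s
#'   (one per starting model).
#' @param pairs List of pairs; each a list with `selA`, `selB` and
#'   optionally `name`.
#' @return data.frame with columns `frame`, `pair`, `mean`, `min`, `max`,
#'   `n_models`.
#' @export
distance_series <- function(models, pairs) {
  out <- list()
  for (pi in seq_along(pairs)) {
    pr <- pairs[[pi]]
    nm <- if (!is.null(pr$name)) pr$name else
      paste0(paste(pr$selA, collapse = ":"), "-",
             paste(pr$selB, collapse = ":"))
    for (f in seq_along(models)) {
      ds <- numeric(0)
      for (m in models[[f]]) {
        d <- tryCatch(backbone_distance(m, pr$selA, pr$selB),
                      error = function(e) {
                        warning(sprintf(
                          "frame %d model %s: %s", f,
                          as.character(m$source), conditionMessage(e)),
                          call. = FALSE)
                        NA_real_
                      })
        if (!is.na(d)) ds <- c(ds, d)
      }
      if (length(ds) == 0)
        stop("frame ", f, " has no model resolving pair ", nm)
      out[[length(out) + 1]] <- data.frame(
        frame = f, pair = nm, mean = mean(ds), min = min(ds),
        max = max(ds), n_models = length(ds))
    }
  }
  do.call(rbind, out)
}
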