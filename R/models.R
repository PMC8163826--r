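#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation and translation mapping the selected atoms of `b` onto
#' those of `a`, with atoms paired by (chain, residue number, atom name).
#' The default selection is all C-alpha atoms.
#'
#' @param a,b `atom_model` tibbles (see [read_model]).
#' @param atom Atom name(s) used for pairing and fitting (default `"CA"`).
#' @param chain,resno Optional selection filters applied to both models.
#' @return List: `R` (3x3 rotation), `t` (translation, applied as
#'   `x %*% t(R) + t`), `rmsd` (angstroms, over the fitted atoms),
#'   `n` (atom pairs), `transformed` (`b` with all its atoms moved).
#' @export
superpose <- function(a, b, atom = "CA", chain = NULL, resno = NULL) {
  sa <- select_atoms(a, chain = chain, resno = resno, atom = atom)
  sb <- select_atoms(b, chain = chain, resno = resno, atom = atom)
  key <- function(m) paste(m$chain, m$resno, m$atom, sep = "|")
  ka <- key(sa); kb <- key(sb)
  common <- intersect(ka, kb)
  miss <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(miss) > 0) {
    stop("unmatched atoms in selection: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) sprintf(" (and %d more)", length(miss) - 10),
         call. = FALSE)
  }
  if (length(common) < 3) stop("need at least 3 paired atoms", call. = FALSE)
  pa <- as.matrix(sa[match(common, ka), c("x", "y", "z")])
  pb <- as.matrix(sb[match(common, kb), c("x", "y", "z")])
  fit <- kabsch(pa, pb)
  moved <- b
  mb <- as.matrix(b[, c("x", "y", "z")])
  mb <- sweep(mb, 2, fit$cb) %*% t(fit$R)
  mb <- sweep(mb, 2, fit$ca, `+`)
  moved$x <- mb[, 1]; moved$y <- mb[, 2]; moved$z <- mb[, 3]
  list(R = fit$R, t = as.vector(fit$ca - fit$R %*% fit$cb), rmsd = fit$rmsd,
       n = length(common), transformed = moved)
}

# Kabsch: rotation R minimizing |(pa - ca) - R (pb - cb)|^2.
kabsch <- function(pa, pb) {
  ca <- colMeans(pa); cb <- colMeans(pb)
  A <- sweep(pa, 2, ca); B <- sweep(pb, 2, cb)
  H <- t(B) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- A - B %*% t(R)
  list(R = R, ca = ca, cb = cb, rmsd = sqrt(mean(rowSums(diffs^2))))
}

rmsd_paired <- function(a, b, atom = "CA", chain = NULL, resno = NULL) {
  sa <- select_atoms(a, chain = chain, resno = resno, atom = atom)
  sb <- select_atoms(b, chain = chain, resno = resno, atom = atom)
  key <- function(m) paste(m$chain, m$resno, m$atom, sep = "|")
  common <- intersect(key(sa), key(sb))
  pa <- as.matrix(sa[match(common, key(sa)), c("x", "y", "z")])
  pb <- as.matrix(sb[match(common, key(sb)), c("x", "y", "z")])
  sqrt(mean(rowSums((pa - pb)^2)))
}

#' Interface specification for pairwise RMSD analysis
#'
#' Defines which atoms are used to superpose two models (the fixed domain)
#' and over which atoms the deviation is then measured across the interface,
#' without re-fitting.
#'
#' @param kind Label, e.g. `"NTD-NTD"`, `"NTD-CTD"`, `"CTD-dimer"`,
#'   `"CTD-trimer"`.
#' @param fixed List of selection arguments (`chain`, `resno`, `atom`) for
#'   the fixed domain.
#' @param measured List (or list of lists) of selection arguments for the
#'   measured domain(s).
#' @return An `interface_spec` list.
#' @export
interface_spec <- function(kind, fixed, measured) {
  structure(list(kind = kind, fixed = fixed, measured = measured),
            class = "interface_spec")
}

apply_sel <- function(model, sel) {
  do.call(select_atoms, c(list(model), sel))
}

#' Pairwise interface RMSD matrix across class models
#'
#' For each model pair the second model is superposed onto the first using
#' the fixed-domain selection; the RMSD is then measured over the measured
#' domain(s) without re-fitting. The matrix is symmetric with zero diagonal
#' (the larger of the two directed values is reported, which for rigid-body
#' fitted models of the same topology coincide).
#'
#' @param models Named list of `atom_model`s.
#' @param spec An [interface_spec].
#' @param atom Atom name used throughout (default `"CA"`).
#' @return Symmetric numeric matrix (angstroms).
#' @export
interface_rmsd_matrix <- function(models, spec, atom = "CA") {
  n <- length(models)
  out <- matrix(0, n, n, dimnames = list(names(models), names(models)))
  measured <- spec$measured
  if (!is.list(measured[[1]])) measured <- list(measured)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    sup <- superpose(models[[i]], models[[j]], atom = atom,
                     chain = spec$fixed$chain, resno = spec$fixed$resno)
    vals <- vapply(measured, function(ms) {
      rmsd_paired(apply_sel(models[[i]], ms), apply_sel(sup$transformed, ms),
                  atom = atom)
    }, numeric(1))
    out[i, j] <- mean(vals)
  }
  pmax(out, t(out))
}

#' C-alpha RMSD of two pentamer models after global superposition
#'
#' Superposes the two models on all shared C-alpha atoms and reports the
#' RMSD, the comparison used to show that pentamers from different assembly
#' forms are essentially identical.
#'
#' @param model_a,model_b `atom_model`s with matching chain/residue
#'   numbering.
#' @return RMSD in angstroms.
#' @export
pentamer_model_rmsd <- function(model_a, model_b) {
  superpose(model_a, model_b, atom = "CA")$rmsd
}
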