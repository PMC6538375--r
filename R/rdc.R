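# RDC analysis: least-squares Saupe tensor via SVD of the direction-cosine
# design matrix, back-calculation, Q-factor and per-model scoring.

# design-matrix row for a unit vector u: D = u' A u with A symmetric
# traceless; unknowns (Ayy, Azz, Axy, Axz, Ayz), Axx = -Ayy - Azz.
.designRow <- function(u) {
  c(u[2L]^2 - u[1L]^2, u[3L]^2 - u[1L]^2,
    2 * u[1L] * u[2L], 2 * u[1L] * u[3L], 2 * u[2L] * u[3L])
}

.saupeFromParams <- function(p) {
  A <- matrix(c(-p[1L] - p[2L], p[3L], p[4L],
                p[3L], p[1L], p[5L],
                p[4L], p[5L], p[2L]), 3L, 3L)
  (A + t(A)) / 2
}

# principal-axis decomposition with |Azz| >= |Ayy| >= |Axx|
.tensorFromSaupe <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  ord <- order(abs(e$values))  # Axx, Ayy, Azz by increasing magnitude
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 1L] <- -vecs[, 1L]
  Da <- vals[3L] / 2
  R <- if (abs(Da) < 1e-12) 0 else (vals[1L] - vals[2L]) / (3 * Da)
  R <- max(0, min(2 / 3, R))
  beta <- acos(max(-1, min(1, vecs[3L, 3L])))
  if (abs(sin(beta)) > 1e-8) {
    alpha <- atan2(vecs[2L, 3L], vecs[1L, 3L])
    gamma <- atan2(vecs[3L, 2L], -vecs[3L, 1L])
  } else {
    alpha <- atan2(vecs[2L, 1L], vecs[1L, 1L])
    gamma <- 0
  }
  new("AlignmentTensor", saupe = A - diag(rep(sum(diag(A)) / 3, 3L)),
      Da = Da, rhombicity = R,
      euler = .rad2deg(c(alpha, beta, gamma)))
}

#' Fit an alignment tensor to observed RDCs by SVD
#'
#' Builds the 5-column direction-cosine design matrix from the model's bond
#' vectors and solves the least-squares Saupe matrix through singular value
#' decomposition (pseudoinverse). N-C' couplings are rescaled to
#' NH-equivalent units by the standard dipolar prefactor ratio before
#' fitting. By default NC records are excluded from the fit and reported as
#' cross-validation, mirroring the practice of reserving one coupling type
#' for structure validation.
#'
#' @param model a \linkS4class{StructureModel}.
#' @param rdcs an \linkS4class{RDCTable}.
#' @param fit_types coupling types entering the fit (default "NH"; excluded
#'   types with records are back-calculated and reported as validation).
#' @param weighted logical: scale rows by 1/sigma when uncertainties are
#'   present.
#' @param cond_warn warn when the design-matrix condition number exceeds
#'   this threshold.
#' @return an \linkS4class{RDCFitReport}.
#' @export
fitTensorSVD <- function(model, rdcs, fit_types = "NH", weighted = FALSE,
                         cond_warn = 1e4) {
  rec <- rdcRecords(rdcs)
  if (nrow(rec) == 0L) stop("empty RDC table")
  vec <- bondVectors(model, unique(rec$type))
  key <- paste(vec$resno, vec$type)
  rec$vi <- match(paste(rec$resno, rec$type), key)
  rec$used <- rec$type %in% fit_types & !is.na(rec$vi)
  rec$reason <- ifelse(is.na(rec$vi), "bond vector unavailable",
                       ifelse(rec$used, "", "validation type"))
  fitrec <- rec[rec$used, , drop = FALSE]
  if (nrow(fitrec) < 5L)
    stop(sprintf("only %d usable records; >= 5 needed to determine the tensor",
                 nrow(fitrec)))
  U <- as.matrix(vec[fitrec$vi, c("ux", "uy", "uz")])
  X <- t(apply(U, 1L, .designRow))
  y <- fitrec$D
  # NC records rescaled to NH-equivalent units
  y[fitrec$type == "NC"] <- y[fitrec$type == "NC"] / .NC_SCALE
  if (weighted && !all(is.na(fitrec$sigma))) {
    w <- 1 / ifelse(is.na(fitrec$sigma), median(fitrec$sigma, na.rm = TRUE),
                    fitrec$sigma)
    X <- X * w
    y <- y * w
  }
  sv <- svd(X)
  cond <- sv$d[1L] / sv$d[5L]
  if (!is.finite(cond) || cond > cond_warn)
    warning(sprintf("ill-conditioned design matrix (condition number %.3g)",
                    cond))
  dinv <- ifelse(sv$d > 1e-12 * sv$d[1L], 1 / sv$d, 0)
  params <- sv$v %*% (dinv * crossprod(sv$u, y))
  A <- .saupeFromParams(as.numeric(params))
  tensor <- .tensorFromSaupe(A)
  # back-calculate every record with an available vector
  rec$D_calc <- NA_real_
  has <- !is.na(rec$vi)
  Uall <- as.matrix(vec[rec$vi[has], c("ux", "uy", "uz")])
  Dc <- rowSums((Uall %*% A) * Uall)
  Dc[rec$type[has] == "NC"] <- Dc[rec$type[has] == "NC"] * .NC_SCALE
  rec$D_calc[has] <- Dc
  used <- rec$used
  rms <- sqrt(mean((rec$D[used] - rec$D_calc[used])^2))
  q <- if (sqrt(mean(rec$D[used]^2)) == 0) NA_real_
       else qFactor(rec$D[used], rec$D_calc[used])
  qv <- NA_real_
  val <- !used & has
  if (any(val) && sqrt(mean(rec$D[val]^2)) > 0)
    qv <- qFactor(rec$D[val], rec$D_calc[val])
  out <- data.frame(resno = rec$resno, type = rec$type, D_obs = rec$D,
                    D_calc = rec$D_calc, used = rec$used,
                    reason = rec$reason)
  new("RDCFitReport", records = out, tensor = tensor, q = q,
      q_validation = qv, rms = rms, condition = cond)
}

#' Back-calculate RDCs from a model and tensor
#'
#' @param model a \linkS4class{StructureModel}.
#' @param tensor an \linkS4class{AlignmentTensor}.
#' @param types coupling types to compute.
#' @return an \linkS4class{RDCTable} of noiseless couplings.
#' @export
backCalculate <- function(model, tensor, types = "NH") {
  simulateRDCs(model, tensor, types = types, noise_sd = 0)
}

#' RDC Q-factor
#'
#' \eqn{Q = \mathrm{rms}(D_{obs} - D_{calc}) / \mathrm{rms}(D_{obs})};
#' lower is better agreement.
#'
#' @param observed,calculated paired numeric vectors in Hz.
#' @return unitless Q.
#' @export
qFactor <- function(observed, calculated) {
  stopifnot(length(observed) == length(calculated), length(observed) > 0L)
  denom <- sqrt(mean(observed^2))
  if (denom == 0) stop("rms of observed couplings is zero")
  sqrt(mean((observed - calculated)^2)) / denom
}

#' Score a model pool by per-model RDC fit quality
#'
#' Each model receives its own alignment-tensor fit (alignment differs per
#' model); models are ranked ascending by Q. Models whose fit fails are
#' ranked last with NA Q.
#'
#' @param pool an \linkS4class{Ensemble} or list of models.
#' @param rdcs an \linkS4class{RDCTable}.
#' @param fit_types coupling types used in the fit.
#' @return data.frame with columns model (index into the pool), q, rms,
#'   sorted ascending by q (NAs last, ties by model index).
#' @export
scoreModels <- function(pool, rdcs, fit_types = "NH") {
  mods <- if (is(pool, "Ensemble")) models(pool) else pool
  rows <- lapply(seq_along(mods), function(m) {
    rep <- try(fitTensorSVD(mods[[m]], rdcs, fit_types = fit_types),
               silent = TRUE)
    if (inherits(rep, "try-error"))
      data.frame(model = m, q = NA_real_, rms = NA_real_)
    else data.frame(model = m, q = rep@q, rms = rep@rms)
  })
  out <- do.call(rbind, rows)
  out[order(is.na(out$q), out$q, out$model), , drop = FALSE]
}
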