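# Hessian-energy regularizer, built in four steps per sample: kNN patch,
# SVD tangent frame, least-squares estimation of second-order (Hessian)
# coefficients, and accumulation of the per-patch quadratic forms into a
# global symmetric PSD matrix H with H 1 = 0. Functions affine in the
# manifold coordinates have zero energy, so Tr(V^T H V) favors components
# that vary linearly along geodesics.

#' Exact Euclidean k-nearest neighborhoods
#'
#' Ties in distance are broken by lower sample index so the construction is
#' deterministic.
#'
#' @param samples n x p numeric matrix (samples in rows)
#' @param kNN neighborhood size, < n
#' @return list with \code{index} (n x kNN integer matrix, ordered by
#'   non-decreasing distance, never containing the query index) and
#'   \code{dist} (matching distances)
#' @export
buildNeighborhoods <- function(samples, kNN = 12L) {
    samples <- as.matrix(samples)
    n <- nrow(samples)
    if (!all(is.finite(samples))) stop("non-finite entries in samples")
    if (kNN >= n) stop("kNN must be < n")
    D <- as.matrix(dist(samples))
    idx <- matrix(0L, n, kNN)
    dd <- matrix(0, n, kNN)
    for (i in seq_len(n)) {
        o <- order(D[i, ], seq_len(n))   # tie-break: lower index first
        o <- o[o != i][seq_len(kNN)]
        idx[i, ] <- o
        dd[i, ] <- D[i, o]
    }
    list(index = idx, dist = dd, kNN = as.integer(kNN))
}

#' Per-sample tangent frames from local SVD
#'
#' Each patch (the sample plus its kNN neighbors) is centered and its top-d
#' right singular directions taken as an orthonormal tangent basis; patch
#' points are expressed in those coordinates (zero mean per dimension by
#' construction). Degenerate patches of rank < d are flagged and completed
#' deterministically with the remaining singular directions (falling back to
#' coordinate axes orthogonalized against the basis found).
#'
#' @param samples n x p matrix
#' @param neighborhoods output of \code{\link{buildNeighborhoods}}
#' @param d intrinsic dimension, <= kNN
#' @return list of frames; each has \code{patch} (global indices, sample
#'   first), \code{centroid}, \code{basis} (p x d orthonormal), \code{coords}
#'   ((kNN+1) x d), \code{rankDeficient}
#' @export
estimateTangentFrames <- function(samples, neighborhoods, d = 2L) {
    samples <- as.matrix(samples)
    kNN <- neighborhoods$kNN
    if (d > kNN) stop("d must be <= kNN")
    n <- nrow(samples)
    lapply(seq_len(n), function(i) {
        patch <- c(i, neighborhoods$index[i, ])
        P <- samples[patch, , drop = FALSE]
        ctr <- colMeans(P)
        Pc <- sweep(P, 2, ctr)
        sv <- svd(Pc)
        tolr <- max(dim(Pc)) * .Machine$double.eps * max(sv$d, 0)
        rk <- sum(sv$d > tolr)
        basis <- sv$v[, seq_len(min(d, ncol(sv$v))), drop = FALSE]
        rankDeficient <- rk < d
        if (ncol(basis) < d) {
            # complete with orthogonalized coordinate axes
            need <- d - ncol(basis)
            cand <- diag(ncol(samples))
            for (j in seq_len(ncol(cand))) {
                if (need == 0) break
                v <- cand[, j] - basis %*% crossprod(basis, cand[, j])
                nv <- sqrt(sum(v^2))
                if (nv > 1e-8) {
                    basis <- cbind(basis, v / nv)
                    need <- need - 1
                }
            }
        }
        basis <- .signFix(basis)
        list(patch = patch, centroid = ctr, basis = basis,
             coords = Pc %*% basis, rankDeficient = rankDeficient)
    })
}

# design matrix: [1 | linear tangent coords | quadratic monomials u_a u_b, a<=b]
.hessianDesign <- function(coords) {
    d <- ncol(coords)
    quad <- NULL
    for (a in seq_len(d)) for (b in a:d)
        quad <- cbind(quad, coords[, a] * coords[, b])
    cbind(1, coords, quad)
}

#' Local Hessian-energy quadratic form of one patch
#'
#' Fits, by least squares, a full quadratic in the tangent coordinates to
#' function values on the patch, and returns the PSD block
#' B = W^T W where W consists of the rows of the design pseudo-inverse that
#' extract the second-order coefficients. Constants and functions linear in
#' the tangent coordinates receive zero energy. Rank-deficient designs are
#' solved through ridge-stabilized normal equations (ridge 1e-8 * trace).
#'
#' @param frame one element of \code{\link{estimateTangentFrames}}'s output
#' @return list with \code{B} ((kNN+1) x (kNN+1) PSD matrix), \code{W},
#'   and \code{ridged} (logical)
#' @export
localHessianEnergy <- function(frame) {
    M <- .hessianDesign(frame$coords)
    d <- ncol(frame$coords)
    qIdx <- (1 + d + 1):ncol(M)
    sv <- svd(M)
    tolr <- max(dim(M)) * .Machine$double.eps * max(sv$d)
    ridged <- FALSE
    if (min(sv$d) > tolr) {
        Mp <- sv$v %*% (t(sv$u) / sv$d)
    } else {
        ridged <- TRUE
        warning("rank-deficient local design; ridge-stabilized pseudo-inverse")
        G <- crossprod(M)
        Mp <- solve(G + 1e-8 * sum(diag(G)) * diag(ncol(M)), t(M))
    }
    W <- Mp[qIdx, , drop = FALSE]
    list(B = crossprod(W), W = W, ridged = ridged)
}

#' Assemble the Hessian-energy graph regularizer
#'
#' Runs the four construction steps and accumulates each patch block into
#' the global n x n matrix, which is then symmetrized and eigenvalue-clipped
#' to be positive semidefinite.
#'
#' @param samples n x p matrix (samples in rows)
#' @param kNN neighborhood size (default 12; keeps the quadratic design
#'   overdetermined for d = 2)
#' @param d intrinsic manifold dimension (default 2)
#' @param psdFloor relative eigenvalue tolerance for clipping
#' @return a \linkS4class{HessianGraph}
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' h <- hessianGraph(x, kNN = 8, d = 2)
#' max(abs(hessianMatrix(h) %*% rep(1, 20)))  # ~0: constants have no energy
#' @export
hessianGraph <- function(samples, kNN = 12L, d = 2L, psdFloor = 1e-8) {
    samples <- as.matrix(samples)
    n <- nrow(samples)
    if (n < kNN + 2) stop("need n >= kNN + 2")
    nb <- buildNeighborhoods(samples, kNN)
    frames <- estimateTangentFrames(samples, nb, d)
    H <- matrix(0, n, n)
    flagged <- integer(0)
    for (i in seq_len(n)) {
        fr <- frames[[i]]
        le <- withCallingHandlers(localHessianEnergy(fr),
            warning = function(w) invokeRestart("muffleWarning"))
        if (fr$rankDeficient || le$ridged) flagged <- c(flagged, i)
        H[fr$patch, fr$patch] <- H[fr$patch, fr$patch] + le$B
    }
    H <- (H + t(H)) / 2
    eg <- eigen(H, symmetric = TRUE)
    if (min(eg$values) < -psdFloor * max(abs(eg$values))) {
        H <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
        H <- (H + t(H)) / 2
    }
    methods::new("HessianGraph", H = H, kNN = as.integer(kNN),
                 d = as.integer(d), psdFloor = psdFloor,
                 flagged = unique(flagged))
}

#' Write / read a Hessian graph as delimited text with metadata
#'
#' @param x a HessianGraph
#' @param path matrix file (CSV)
#' @param metaPath sidecar key=value metadata file
#' @return \code{readHessianGraph} returns a HessianGraph
#' @export
writeHessianGraph <- function(x, path, metaPath = paste0(path, ".meta")) {
    stopifnot(is(x, "HessianGraph"))
    write.table(format(x@H, digits = 17, scientific = TRUE, trim = TRUE),
                path, sep = ",", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    writeLines(c(sprintf("kNN=%d", x@kNN), sprintf("d=%d", x@d),
                 sprintf("psdFloor=%.17g", x@psdFloor)), metaPath)
    invisible(path)
}

#' @rdname writeHessianGraph
#' @export
readHessianGraph <- function(path, metaPath = paste0(path, ".meta")) {
    H <- as.matrix(read.csv(path, header = FALSE))
    dimnames(H) <- NULL
    H <- (H + t(H)) / 2
    meta <- strsplit(readLines(metaPath), "=", fixed = TRUE)
    kv <- stats::setNames(vapply(meta, `[`, "", 2),
                          vapply(meta, `[`, "", 1))
    methods::new("HessianGraph", H = H, kNN = as.integer(kv[["kNN"]]),
                 d = as.integer(kv[["d"]]),
                 psdFloor = as.numeric(kv[["psdFloor"]]), flagged = integer(0))
}
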