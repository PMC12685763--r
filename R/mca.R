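# Multiple correspondence analysis of contact events: correspondence
# analysis of the 0/1 indicator matrix over the categorical event
# descriptors, with cos2 and contribution diagnostics and a quadrant-based
# typology assignment on the first two dimensions.

#' Build the indicator matrix for contact-event MCA
#'
#' One 0/1 column per observed category; each row sums to the number of
#' variables. Binary numeric columns are mapped to absent/present levels.
#'
#' @param events Classified event tibble (see [classify_event]).
#' @param variables Character vector of descriptor columns (default: the
#'   six used by the typology analysis, giving J = 14 categories when all
#'   levels occur).
#' @return Indicator matrix with `Q` (number of variables) and `var`
#'   (column-to-variable map) attributes. Declared-but-unobserved factor
#'   levels are dropped with a warning; missing values are an error.
#' @export
build_indicator <- function(events,
                            variables = c("duration_class", "sex_pair",
                                          "time_class", "anthropogenic",
                                          "natural", "denning_tree")) {
  stopifnot(all(variables %in% names(events)))
  cols <- list(); varmap <- character()
  for (v in variables) {
    x <- events[[v]]
    if (anyNA(x))
      stop("missing level for variable '", v, "' at event(s) ",
           paste(utils::head(which(is.na(x)), 5), collapse = ", "))
    if (is.numeric(x)) {
      if (!all(x %in% 0:1)) stop("numeric variable '", v, "' must be 0/1")
      x <- factor(ifelse(x == 1, "present", "absent"),
                  levels = c("absent", "present"))
    }
    x <- as.factor(x)
    for (lv in levels(x)) {
      col <- as.integer(x == lv)
      if (sum(col) == 0) {
        warning("level '", lv, "' of '", v, "' never observed: dropped")
        next
      }
      cols[[paste(v, lv, sep = ".")]] <- col
      varmap[paste(v, lv, sep = ".")] <- v
    }
  }
  Z <- do.call(cbind, cols)
  rownames(Z) <- NULL
  attr(Z, "Q") <- length(variables)
  attr(Z, "var") <- varmap
  Z
}

#' Run MCA on an indicator matrix
#'
#' Correspondence analysis of the indicator matrix: with correspondence
#' matrix `P = Z / sum(Z)`, row/column masses `r`, `c`, the standardized
#' residuals `S = Dr^(-1/2) (P - r c') Dc^(-1/2)` are decomposed by SVD;
#' eigenvalues are squared singular values, coordinates are mass-scaled
#' singular vectors. Total inertia over the nontrivial dimensions equals
#' `(J - Q) / Q`. Axis signs are normalized (when the anchor categories
#' exist) so that anthropogenic presence loads negative on dimension 1 and
#' long duration positive on dimension 2, making quadrant semantics stable
#' across platforms.
#'
#' @param Z Indicator matrix from [build_indicator].
#' @param orient Apply the sign-orientation rule.
#' @param anchor_neg_dim1,anchor_pos_dim2 Category column names anchoring
#'   the axis orientations.
#' @return An `mca_result`: `eigenvalues`, `percent_variance`,
#'   `cat_coords`, `row_coords`, `cos2`, `contrib` (%), `masses`, `Q`, `J`,
#'   `n`, `total_inertia`.
#' @export
run_mca <- function(Z, orient = TRUE,
                    anchor_neg_dim1 = "anthropogenic.present",
                    anchor_pos_dim2 = "duration_class.long") {
  n <- nrow(Z); J <- ncol(Z); Q <- attr(Z, "Q")
  if (is.null(Q)) Q <- sum(Z[1, ])
  if (n < J) stop("need at least as many events as categories")
  P <- Z / sum(Z)
  r <- rowSums(P); cm <- colSums(P)
  S <- sweep(sweep(P - outer(r, cm), 1, sqrt(r), "/"), 2, sqrt(cm), "/")
  sv <- svd(S)
  pos <- sv$d > 1e-10
  d <- sv$d[pos]
  lambda <- d^2
  G <- sweep(sv$v[, pos, drop = FALSE] %*% diag(d, sum(pos)), 1,
             sqrt(cm), "/")
  F_ <- sweep(sv$u[, pos, drop = FALSE] %*% diag(d, sum(pos)), 1,
              sqrt(r), "/")
  rownames(G) <- colnames(Z)
  if (orient) {
    flip <- rep(1, ncol(G))
    if (anchor_neg_dim1 %in% rownames(G) && G[anchor_neg_dim1, 1] > 0)
      flip[1] <- -1
    if (ncol(G) >= 2 && anchor_pos_dim2 %in% rownames(G) &&
        G[anchor_pos_dim2, 2] < 0)
      flip[2] <- -1
    G <- sweep(G, 2, flip, "*")
    F_ <- sweep(F_, 2, flip, "*")
  }
  d2 <- rowSums(G^2)                    # squared chi-distance to centroid
  cos2 <- G^2 / d2
  contrib <- 100 * sweep(G^2 * cm, 2, lambda, "/")
  total <- sum(lambda)
  structure(list(
    eigenvalues = lambda,
    percent_variance = 100 * lambda / total,
    cat_coords = G, row_coords = F_, cos2 = cos2, contrib = contrib,
    masses = cm, Q = Q, J = J, n = n, total_inertia = total),
    class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("<mca_result> n = %d events, Q = %d variables, J = %d categories\n",
              x$n, x$Q, x$J))
  k <- min(4, length(x$eigenvalues))
  cat("  eigenvalues:",
      paste(sprintf("%.3f (%.1f%%)", x$eigenvalues[1:k],
                    x$percent_variance[1:k]), collapse = ", "), "\n")
  invisible(x)
}

#' Percent variance implied by an eigenvalue under the indicator convention
#'
#' The share of the indicator-matrix total inertia `(J - Q) / Q` carried by
#' one eigenvalue (no Benzecri/Greenacre correction).
#'
#' @param eigenvalue Principal eigenvalue(s).
#' @param Q Number of variables.
#' @param J Total number of categories.
#' @return Percent of total inertia.
#' @export
mca_percent_variance <- function(eigenvalue, Q = 6, J = 14) {
  100 * eigenvalue / ((J - Q) / Q)
}

#' Assign quadrant-based contact typologies
#'
#' Events are labelled by the sign pattern of their coordinates on two MCA
#' dimensions (after orientation): (+,+) Type I, (-,+) Type II, (+,-)
#' Type III, and (-,-) or on-axis events unassigned.
#'
#' @param result An `mca_result`.
#' @param dims Pair of dimension indices.
#' @return Factor of typology labels, one per event.
#' @export
assign_typologies <- function(result, dims = c(1, 2)) {
  if (max(dims) > ncol(result$row_coords))
    stop("requested dimensions exceed the MCA rank")
  a <- result$row_coords[, dims[1]]
  b <- result$row_coords[, dims[2]]
  lab <- rep("unassigned", length(a))
  lab[a > 0 & b > 0] <- "Type I"
  lab[a < 0 & b > 0] <- "Type II"
  lab[a > 0 & b < 0] <- "Type III"
  factor(lab, levels = c("Type I", "Type II", "Type III", "unassigned"))
}
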