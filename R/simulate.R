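#' Generate source/target weight matrices with prescribed task similarity
#'
#' Constructs a source map \eqn{\omega_s} with orthonormal rows and a target
#' map \eqn{\omega_t} whose component outside the row space of
#' \eqn{\omega_s} has squared Frobenius norm exactly \code{eps_target},
#' while \eqn{\|\omega_t\|_F = } \code{norm_wt}. This gives direct control
#' over the task-similarity term \eqn{\varepsilon} entering the projected
#' risk formula.
#'
#' @param d Ambient dimension.
#' @param c_s,c_t Source and target label dimensions; \code{c_s < d} so an
#'   off-row-space component exists.
#' @param eps_target Desired \eqn{\varepsilon \in [0, \mathrm{norm\_wt}^2]}.
#' @param norm_wt Desired Frobenius norm of \eqn{\omega_t}.
#' @param seed Integer seed.
#' @return A list with components \code{omega_s} and \code{omega_t}.
#' @export
gen_weights_with_epsilon <- function(d, c_s, c_t, eps_target = 0,
                                     norm_wt = 1, seed = 1L) {
  if (c_s >= d) stop("`c_s` must be smaller than `d`", call. = FALSE)
  if (eps_target < 0 || eps_target > norm_wt^2) {
    stop("`eps_target` must lie in [0, norm_wt^2]", call. = FALSE)
  }
  set.seed(seed)
  A <- matrix(stats::rnorm(c_s * d), c_s, d)
  omega_s <- t(qr.Q(qr(t(A))))                 # orthonormal rows
  B <- matrix(stats::rnorm(c_t * d), c_t, d)
  inside <- B %*% crossprod(omega_s)           # row-space component
  outside <- B - inside
  n_in <- sum(inside^2); n_out <- sum(outside^2)
  if (eps_target > 0 && n_out <= 0) {
    stop("degenerate draw: no off-row-space component available", call. = FALSE)
  }
  in_sq <- norm_wt^2 - eps_target
  inside <- if (in_sq > 0) inside * sqrt(in_sq / n_in) else inside * 0
  outside <- if (eps_target > 0) outside * sqrt(eps_target / n_out)
             else outside * 0
  list(omega_s = omega_s, omega_t = inside + outside)
}

#' Draw an isotropic linear transfer dataset
#'
#' Samples source and target design matrices with i.i.d. standard normal
#' columns (samples are columns, matching the theory orientation) and forms
#' noiseless labels under the task's oracle maps.
#'
#' @param task A [linear_transfer_task()].
#' @param seed Integer seed; output is a pure function of seed and task.
#' @return A list with \code{X_s} (\eqn{d \times n_s}), \code{y_s}
#'   (\eqn{c_s \times n_s}), \code{X_t}, \code{y_t}.
#' @export
gen_isotropic_linear <- function(task, seed = 1L) {
  stopifnot(inherits(task, "linear_transfer_task"))
  set.seed(seed)
  X_s <- matrix(stats::rnorm(task$d * task$n_s), task$d, task$n_s)
  X_t <- matrix(stats::rnorm(task$d * task$n_t), task$d, task$n_t)
  list(X_s = X_s, y_s = task$omega_s %*% X_s,
       X_t = X_t, y_t = task$omega_t %*% X_t)
}

#' Clustered classification tasks with source-to-target class refinement
#'
#' Emulates transfer between image-classification tasks where the source
#' classes refine the target classes (each target class is a union of
#' source classes, as when a 1000-class source contains every 10-class
#' target category). Source class centers are drawn uniformly on the unit
#' sphere in dimension \code{d}; samples are isotropic Gaussian blobs of
#' per-coordinate standard deviation \code{cluster_sd} around their center,
#' so \code{cluster_sd} alone controls class separation. Target samples are
#' drawn from the union of the blobs mapped to each target class. Classes
#' are balanced up to rounding. Labels are one-hot.
#'
#' @param n_source_classes,n_target_classes Class counts.
#' @param class_map A list of length \code{n_target_classes} whose k-th
#'   element is the vector of source classes composing target class k; must
#'   cover every target class. Defaults to a balanced partition of the
#'   source classes in order.
#' @param d Feature dimension.
#' @param cluster_sd Per-coordinate blob standard deviation.
#' @param n_s,n_t,n_test Source-train, target-train and target-test sample
#'   counts.
#' @param seed Integer seed.
#' @return A list with elements \code{source} (\code{X}, \code{Y},
#'   \code{class}), \code{target} and \code{test} (same structure, target
#'   labels), plus \code{centers} and \code{class_map}.
#' @export
gen_clustered_classification <- function(n_source_classes = 20,
                                         n_target_classes = 5,
                                         class_map = NULL,
                                         d = 30, cluster_sd = 0.35,
                                         n_s = 2000, n_t = 50,
                                         n_test = 500, seed = 1L) {
  if (is.null(class_map)) {
    class_map <- split(seq_len(n_source_classes),
                       rep(seq_len(n_target_classes),
                           length.out = n_source_classes))
  }
  if (length(class_map) != n_target_classes ||
      any(vapply(class_map, length, 1L) == 0L)) {
    stop("`class_map` must assign at least one source class to every target class",
         call. = FALSE)
  }
  if (n_s < n_source_classes || n_t < n_target_classes) {
    stop("sample counts must be at least the class counts", call. = FALSE)
  }
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_source_classes * d), n_source_classes, d)
  centers <- centers / sqrt(rowSums(centers^2))
  draw_blobs <- function(src_class) {
    n <- length(src_class)
    centers[src_class, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = cluster_sd), n, d)
  }
  src_class <- rep_len(seq_len(n_source_classes), n_s)
  source <- list(X = draw_blobs(src_class),
                 Y = one_hot(src_class, n_source_classes),
                 class = src_class)
  draw_target <- function(n) {
    tgt_class <- rep_len(seq_len(n_target_classes), n)
    src <- vapply(tgt_class, function(k) {
      blobs <- class_map[[k]]
      blobs[sample.int(length(blobs), 1L)]
    }, 1L)
    list(X = draw_blobs(src), Y = one_hot(tgt_class, n_target_classes),
         class = tgt_class)
  }
  list(source = source, target = draw_target(n_t),
       test = draw_target(n_test), centers = centers,
       class_map = class_map)
}

#' Drug-screen simulation configuration
#'
#' Describes a synthetic drug-by-cell-line expression screen with the
#' structure virtual drug screening exploits: drug effects largely shared
#' across cell lines, modulated by a cell-specific interaction. Each cell
#' line carries a latent vector \eqn{u_c} and each drug a latent vector
#' \eqn{v_p} (both of dimension \code{rank}); the control (unperturbed)
#' expression of a cell line is \eqn{G_0 u_c} and the perturbed expression
#' of combination \eqn{(c, p)} is
#' \deqn{G_0 u_c + G_d v_p + \gamma\, G_i (u_c \odot v_p) + \textrm{noise},}
#' where \eqn{G_d v_p} is the shared drug signature and the Hadamard term
#' is the cell-specific modulation of strength
#' \eqn{\gamma = } \code{interaction}. Drug fingerprints are
#' sign-thresholded random projections of \eqn{v_p} — a binary stand-in for
#' 1024-bit circular chemical fingerprints, shared across cell lines. Model
#' inputs are the concatenation \code{[control expression | fingerprint]}.
#'
#' @param n_cell_lines,n_drugs Numbers of cell lines and drugs.
#' @param n_genes Output (gene) dimension.
#' @param fp_bits Fingerprint length in bits.
#' @param rank Latent dimension of the response; at most
#'   \code{min(n_genes, fp_bits)}.
#' @param interaction Relative strength \eqn{\gamma} of the cell-specific
#'   interaction term against the shared drug signature.
#' @param noise_sd Additive expression noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class \code{drug_screen_sim}.
#' @export
drug_screen_sim <- function(n_cell_lines = 10, n_drugs = 120, n_genes = 50,
                            fp_bits = 32, rank = 8, interaction = 0.5,
                            noise_sd = 0.25, seed = 1L) {
  if (rank > min(n_genes, fp_bits)) {
    stop("`rank` must be at most min(n_genes, fp_bits)", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  structure(list(n_cell_lines = n_cell_lines, n_drugs = n_drugs,
                 n_genes = n_genes, fp_bits = fp_bits, rank = rank,
                 interaction = interaction, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "drug_screen_sim")
}

#' Generate a synthetic drug screen with held-out cell lines and drugs
#'
#' Realizes a [drug_screen_sim()] and splits it the way the transfer
#' experiments are organized: the source task contains all non-held-out
#' cell lines crossed with the "seen" drugs; each held-out cell line
#' becomes a target task whose samples are stratified by whether the drug
#' also appears in the source data (\code{seen}) or is entirely new
#' (\code{unseen}).
#'
#' @param sim A [drug_screen_sim()].
#' @param held_out_cells Number of cell lines reserved for target tasks.
#' @param held_out_drugs Number of drugs excluded from the source task.
#' @return A list with \code{source} (\code{X}, \code{Y}, \code{cell},
#'   \code{drug}), \code{targets} (one element per held-out cell line, each
#'   with \code{seen} and \code{unseen} strata carrying \code{X}, \code{Y},
#'   \code{drug}), and \code{controls} (per-cell control expression,
#'   cell lines in rows).
#' @export
gen_drug_screen <- function(sim, held_out_cells = 2, held_out_drugs = 24) {
  stopifnot(inherits(sim, "drug_screen_sim"))
  if (held_out_cells >= sim$n_cell_lines || held_out_drugs >= sim$n_drugs) {
    stop("held-out counts must be below the totals", call. = FALSE)
  }
  set.seed(sim$seed)
  r <- sim$rank
  U <- matrix(stats::rnorm(r * sim$n_cell_lines), r, sim$n_cell_lines)
  V <- matrix(stats::rnorm(r * sim$n_drugs), r, sim$n_drugs)
  G0 <- matrix(stats::rnorm(sim$n_genes * r), sim$n_genes, r) / sqrt(r)
  Gd <- matrix(stats::rnorm(sim$n_genes * r), sim$n_genes, r) / sqrt(r)
  Gi <- matrix(stats::rnorm(sim$n_genes * r), sim$n_genes, r) / sqrt(r)
  R <- matrix(stats::rnorm(sim$fp_bits * r), sim$fp_bits, r)
  controls <- t(G0 %*% U)                          # cell lines in rows
  fps <- t((R %*% V) > 0) * 1                      # drugs in rows, 0/1
  make_table <- function(cells, drugs) {
    combos <- expand.grid(drug = drugs, cell = cells)
    X <- cbind(controls[combos$cell, , drop = FALSE],
               fps[combos$drug, , drop = FALSE])
    effect <- t(Gd %*% V[, combos$drug, drop = FALSE]) +
      sim$interaction * t(Gi %*% (U[, combos$cell, drop = FALSE] *
                                    V[, combos$drug, drop = FALSE]))
    Y <- controls[combos$cell, , drop = FALSE] + effect
    if (sim$noise_sd > 0) {
      Y <- Y + matrix(stats::rnorm(length(Y), sd = sim$noise_sd),
                      nrow(Y), ncol(Y))
    }
    list(X = X, Y = Y, cell = combos$cell, drug = combos$drug)
  }
  source_cells <- seq_len(sim$n_cell_lines - held_out_cells)
  target_cells <- setdiff(seq_len(sim$n_cell_lines), source_cells)
  seen_drugs <- seq_len(sim$n_drugs - held_out_drugs)
  unseen_drugs <- setdiff(seq_len(sim$n_drugs), seen_drugs)
  targets <- lapply(target_cells, function(cc) {
    list(cell = cc,
         seen = make_table(cc, seen_drugs),
         unseen = make_table(cc, unseen_drugs))
  })
  names(targets) <- paste0("cell_", target_cells)
  list(source = make_table(source_cells, seen_drugs),
       targets = targets, controls = controls, fingerprints = fps,
       seen_drugs = seen_drugs, unseen_drugs = unseen_drugs, sim = sim)
}
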