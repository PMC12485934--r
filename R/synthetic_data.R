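#' Opening specification for synthetic shells
#'
#' @param direction length-3 vector; the opening is centered where this
#'   direction pierces the shell.
#' @param width_deg angular width in degrees.
#' @param shape `"slit"` (a band along a great circle, `length_deg` long)
#'   or `"circular"` (a cone).
#' @param length_deg slit length in degrees (default `3 * width_deg`).
#' @return list of class `opening_spec`.
#' @export
opening_spec <- function(direction, width_deg, shape = c("slit", "circular"),
                         length_deg = NULL) {
  shape <- match.arg(shape)
  stopifnot(length(direction) == 3, width_deg > 0)
  structure(list(direction = direction / sqrt(sum(direction^2)),
                 width_deg = width_deg, shape = shape,
                 length_deg = length_deg %||% (3 * width_deg)),
            class = "opening_spec")
}

#' Shell specification for synthetic cage assemblies
#'
#' Describes a hollow ellipsoidal shell built from pseudo-atoms, the
#' geometric stand-in for a cage-like protein assembly (a flattened hollow
#' ellipsoid roughly 22 x 16 x 12 nm outside with a 2 nm wall).
#'
#' @param axes_nm outer full axes (a, b, c) in nm; default `c(22, 16, 12)`.
#' @param thickness_nm wall thickness in nm; must be below half the
#'   smallest axis. Default 2.
#' @param spacing pseudo-atom spacing on each layer, Angstrom; default 4
#'   (twice the 2 Angstrom pseudo-atom radius class, giving a closed wall).
#' @param openings list of [opening_spec()]s.
#' @param seed RNG seed (used for the tangential jitter of pseudo-atoms).
#' @return list of class `shell_spec`.
#' @export
shell_spec <- function(axes_nm = c(22, 16, 12), thickness_nm = 2, spacing = 4,
                       openings = list(), seed = 1) {
  stopifnot(length(axes_nm) == 3, all(axes_nm > 0), spacing > 0)
  if (!(thickness_nm < min(axes_nm) / 2)) {
    stop("thickness must be < min(axes)/2")
  }
  structure(list(axes_nm = axes_nm, thickness_nm = thickness_nm,
                 spacing = spacing, openings = openings, seed = seed),
            class = "shell_spec")
}

# deterministic, roughly uniform points on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

# Knud Thomsen approximation of ellipsoid surface area (semi-axes)
ellipsoid_area <- function(a, b, c) {
  p <- 1.6075
  4 * pi * (((a * b)^p + (a * c)^p + (b * c)^p) / 3)^(1 / p)
}

in_opening <- function(u, op) {
  d <- op$direction
  ang_to_center <- acos(pmin(1, pmax(-1, u %*% d)))
  if (op$shape == "circular") {
    return(as.vector(ang_to_center) < op$width_deg * pi / 360)
  }
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t <- ref - sum(ref * d) * d
  t <- t / sqrt(sum(t^2))
  nrm <- c(d[2] * t[3] - d[3] * t[2], d[3] * t[1] - d[1] * t[3],
           d[1] * t[2] - d[2] * t[1])
  off_band <- asin(pmin(1, pmax(-1, abs(u %*% nrm))))
  as.vector(off_band) < op$width_deg * pi / 360 &
    as.vector(ang_to_center) < op$length_deg * pi / 360
}

#' Generate a hollow shell assembly with known ground truth
#'
#' Places pseudo-atoms on concentric ellipsoidal layers spanning the wall
#' (layers every two atom radii, so the wall is closed to the probe), cut
#' by any opening masks, and assembles them into a D2-symmetric
#' homotetramer: chain A is the (y > 0, z > 0) quadrant and chains B, C, D
#' its images under the three two-fold rotations, sharing chain A's residue
#' numbering. The innermost layer sits one atom radius inside the inner
#' wall face, so the empty cavity boundary coincides with the ground-truth
#' inner ellipsoid.
#'
#' @param spec a [shell_spec()].
#' @param radius_class pseudo-atom radius in Angstrom; default 2.
#' @return list with `model` (an [atomic_model()]) and `truth`, a list
#'   holding `cavity_axes` (nm, descending), `cavity_volume` (nm^3, the
#'   closed-form inner-ellipsoid volume), `interior_residues` and
#'   `exterior_residues` (data.frames of chain/resno on the inner- and
#'   outermost layers), and `opening_count`.
#' @export
gen_shell <- function(spec, radius_class = 2.0) {
  stopifnot(inherits(spec, "shell_spec"))
  semi_out <- spec$axes_nm * 10 / 2
  t_A <- spec$thickness_nm * 10
  semi_in <- semi_out - t_A
  offs <- unique(c(seq(radius_class, t_A - radius_class, by = 2 * radius_class),
                   t_A - radius_class))
  pts <- with_seed(spec$seed, {
    out <- lapply(seq_along(offs), function(li) {
      semi <- semi_in + offs[li]
      n <- max(64L, round(ellipsoid_area(semi[1], semi[2], semi[3]) / spec$spacing^2))
      u <- fibonacci_sphere(n)
      # seeded tangential jitter breaks lattice artifacts
      u <- u + matrix(stats::rnorm(3 * n, sd = 0.02), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      p <- sweep(u, 2, semi, "*")
      keep <- u[, 2] > 0 & u[, 3] > 0
      cbind(p[keep, , drop = FALSE], layer = li)
    })
    do.call(rbind, out)
  })
  n_res <- nrow(pts)
  rots <- list(A = diag(3),
               B = diag(c(-1, -1, 1)),
               C = diag(c(-1, 1, -1)),
               D = diag(c(1, -1, -1)))
  res <- do.call(rbind, lapply(names(rots), function(ch) {
    xyz <- pts[, 1:3, drop = FALSE] %*% rots[[ch]]
    data.frame(chain = ch, resno = seq_len(n_res), resname = "SHL",
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               layer = pts[, "layer"], stringsAsFactors = FALSE)
  }))
  # carve openings on the assembled shell
  if (length(spec$openings)) {
    u_all <- as.matrix(res[, c("x", "y", "z")])
    u_all <- u_all / sqrt(rowSums(u_all^2))
    cut <- rep(FALSE, nrow(res))
    for (op in spec$openings) cut <- cut | in_opening(u_all, op)
    res <- res[!cut, , drop = FALSE]
  }
  check_porosity(res, spec$spacing)
  layer <- res$layer
  res$layer <- NULL
  model <- atomic_model(res, model_id = "synthetic_shell",
                        radius_class = radius_class)
  inner_axes <- sort(2 * semi_in, decreasing = TRUE) / 10
  truth <- list(
    cavity_axes = inner_axes,
    cavity_volume = ellipsoid_volume(inner_axes[1], inner_axes[2], inner_axes[3]),
    interior_residues = res[layer == 1L, c("chain", "resno")],
    exterior_residues = res[layer == max(layer), c("chain", "resno")],
    opening_count = length(spec$openings),
    seed = spec$seed)
  rownames(truth$interior_residues) <- rownames(truth$exterior_residues) <- NULL
  list(model = model, truth = truth)
}

# nearest-neighbor gap check via a cell list; a wall whose points sit more
# than two spacings apart is porous to any sensible probe
check_porosity <- function(res, spacing) {
  p <- as.matrix(res[, c("x", "y", "z")])
  if (nrow(p) < 2) stop("wall is porous: too few pseudo-atoms")
  cell <- 2 * spacing
  key <- paste(floor(p[, 1] / cell), floor(p[, 2] / cell), floor(p[, 3] / cell))
  # subsample for the check; fibonacci layers are uniform so 500 points suffice
  take <- unique(round(seq(1, nrow(p), length.out = min(500, nrow(p)))))
  worst <- 0
  for (i in take) {
    ki <- strsplit(key[i], " ")[[1]]
    kx <- as.numeric(ki)
    nb <- abs(floor(p[, 1] / cell) - kx[1]) <= 1 &
      abs(floor(p[, 2] / cell) - kx[2]) <= 1 &
      abs(floor(p[, 3] / cell) - kx[3]) <= 1
    nb[i] <- FALSE
    if (!any(nb)) { worst <- Inf; break }
    d2 <- colSums((t(p[nb, , drop = FALSE]) - p[i, ])^2)
    worst <- max(worst, sqrt(min(d2)))
  }
  if (worst > 2 * spacing) {
    stop(sprintf("wall is porous: nearest-neighbor gap %.1f A exceeds 2 x spacing", worst))
  }
  invisible(worst)
}

#' Generate a PAE matrix with planted domain blocks
#'
#' Entry (i, j) is drawn around `within_mean` when i and j share a planted
#' domain and around `between_mean` otherwise (linker residues always draw
#' from `between_mean`), with Gaussian noise, clipped to `[0, 31.75]` - the
#' conventional ceiling of public predictor databases. Non-contiguous
#' domains are supported.
#'
#' @param partition a [domain_partition()] of length `n` (0 = linker).
#' @param n residue count.
#' @param within_mean,between_mean block means in Angstrom;
#'   `between_mean > within_mean >= 0`. Defaults 4 and 25, typical of a
#'   confidently predicted multi-domain chain.
#' @param noise_sd Gaussian noise, Angstrom; default 2.
#' @param seed RNG seed.
#' @return a [pae_matrix()].
#' @export
gen_pae <- function(partition, n, within_mean = 4, between_mean = 25,
                    noise_sd = 2, seed = 1) {
  stopifnot(between_mean > within_mean, within_mean >= 0, noise_sd >= 0)
  a <- as.integer(partition)
  if (length(a) != n) stop("partition index out of range: length must equal n")
  same <- outer(a, a, "==") & a > 0
  with_seed(seed, {
    m <- ifelse(same, within_mean, between_mean) +
      matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    pae_matrix(pmin(pmax(m, 0), 31.75))
  })
}

#' Generate cross-links with planted satisfaction labels
#'
#' Rejection-samples residue pairs on a model until exactly `n_satisfied`
#' pairs whose minimum C-alpha distance over all intra/inter chain
#' assignments is at or below `threshold`, and `n_violated` pairs beyond
#' it, have been planted. Sampling stops with an infeasibility error after
#' 10,000 attempts per requested link.
#'
#' @param model an [atomic_model()] (chains share one numbering).
#' @param n_satisfied,n_violated planted counts.
#' @param threshold distance restraint in Angstrom; default 35.
#' @param seed RNG seed.
#' @param protein protein identifier written into the table; default the
#'   model id.
#' @return list with `table` (a [crosslink_table()]) and `truth`, a
#'   data.frame with the canonical pairs, their minimum distances and
#'   `satisfied` labels.
#' @export
gen_crosslinks <- function(model, n_satisfied, n_violated, threshold = 35,
                           seed = 1, protein = model$model_id) {
  r <- model$residues[!is.na(model$residues$x), ]
  if (nrow(r) < 2) stop("model needs >= 2 residues with C-alpha")
  chains <- chain_ids(model)
  coords <- lapply(chains, ca_coords, model = model)
  universe <- sort(unique(r$resno))
  min_dist <- function(ra, rb) {
    best <- Inf
    for (ca in seq_along(coords)) {
      if (!as.character(ra) %in% rownames(coords[[ca]])) next
      pa <- coords[[ca]][as.character(ra), ]
      for (cb in seq_along(coords)) {
        if (!as.character(rb) %in% rownames(coords[[cb]])) next
        pb <- coords[[cb]][as.character(rb), ]
        best <- min(best, sqrt(sum((pa - pb)^2)))
      }
    }
    best
  }
  n_total <- n_satisfied + n_violated
  max_attempts <- 10000 * max(1, n_total)
  with_seed(seed, {
    sat <- list(); vio <- list(); seen <- character(0)
    attempts <- 0
    while ((length(sat) < n_satisfied || length(vio) < n_violated) &&
           attempts < max_attempts) {
      attempts <- attempts + 1
      pr <- sort(sample(universe, 2))
      key <- paste(pr, collapse = "-")
      if (key %in% seen) next
      d <- min_dist(pr[1], pr[2])
      if (!is.finite(d)) next
      if (d <= threshold && length(sat) < n_satisfied) {
        seen <- c(seen, key)
        sat[[length(sat) + 1]] <- c(pr, d)
      } else if (d > threshold && length(vio) < n_violated) {
        seen <- c(seen, key)
        vio[[length(vio) + 1]] <- c(pr, d)
      }
    }
    if (length(sat) < n_satisfied || length(vio) < n_violated) {
      stop("infeasible cross-link request: attempt budget exhausted")
    }
    rows <- do.call(rbind, c(sat, vio))
    truth <- data.frame(protein_a = protein, res_a = as.integer(rows[, 1]),
                        protein_b = protein, res_b = as.integer(rows[, 2]),
                        distance = rows[, 3],
                        satisfied = rep(c(TRUE, FALSE), c(length(sat), length(vio))),
                        stringsAsFactors = FALSE)
    list(table = crosslink_table(truth[, 1:4], quiet = TRUE), truth = truth)
  })
}

#' Commercial gel-filtration standard kit
#'
#' The classic high-molecular-weight kit: a void marker (Blue Dextran) and
#' four globular standards.
#'
#' @return data.frame with `name` and `mw_kda`.
#' @export
sec_standards <- function() {
  data.frame(name = c("Blue Dextran", "Thyroglobulin", "Apoferritin",
                      "Alcohol dehydrogenase", "Serum albumin"),
             mw_kda = c(2000, 669, 443, 150, 66),
             stringsAsFactors = FALSE)
}

#' Generate a SEC elution table from a log-linear law
#'
#' Elution volume of each standard is `(log10(MW) - intercept) / slope`
#' plus Gaussian noise; an unlabeled unknown row is appended. Default
#' slope/intercept emulate a preparative gel-filtration column resolving
#' megadalton complexes.
#'
#' @param slope per-mL slope of `log10(MW)` vs elution volume; must be
#'   negative (larger species elute earlier). Default -0.05.
#' @param intercept dimensionless intercept; default 6.
#' @param standards data.frame `name`, `mw_kda`; default [sec_standards()].
#' @param noise_sd elution noise in mL; default 0.1.
#' @param unknown_mw true mass of the unknown in kDa.
#' @param seed RNG seed.
#' @return list with `table` (data.frame `name`, `mw_kda`, `ve_ml`; the
#'   unknown row has `mw_kda = NA`) and `truth` (`unknown_mw`, `slope`,
#'   `intercept`, `unknown_ve`).
#' @export
gen_sec <- function(slope = -0.05, intercept = 6, standards = sec_standards(),
                    noise_sd = 0.1, unknown_mw, seed = 1) {
  if (slope >= 0) stop("slope must be negative (larger species elute earlier)")
  if (any(standards$mw_kda <= 0) || unknown_mw <= 0) stop("non-positive MW")
  with_seed(seed, {
    ve <- (log10(standards$mw_kda) - intercept) / slope +
      stats::rnorm(nrow(standards), sd = noise_sd)
    ve_unk <- (log10(unknown_mw) - intercept) / slope + stats::rnorm(1, sd = noise_sd)
    tab <- rbind(data.frame(name = standards$name, mw_kda = standards$mw_kda,
                            ve_ml = ve, stringsAsFactors = FALSE),
                 data.frame(name = "unknown", mw_kda = NA_real_, ve_ml = ve_unk))
    rownames(tab) <- NULL
    list(table = tab,
         truth = list(unknown_mw = unknown_mw, slope = slope,
                      intercept = intercept, unknown_ve = ve_unk))
  })
}

#' Generate an aligned sequence pair of specified identity
#'
#' The second sequence is the first with a seeded random subset of
#' positions substituted (no gaps), so the realized identity is within
#' `1/length` of the target. Identity counts substituted columns only.
#'
#' @param length sequence length (>= 20).
#' @param target_identity fraction in `(0, 1]`.
#' @param seed RNG seed.
#' @return list with `seqs` (named character vector `A`, `B`) and
#'   `realized_identity`.
#' @export
gen_seq_pair <- function(length, target_identity, seed = 1) {
  if (length < 20) stop("length must be >= 20")
  if (target_identity <= 0 || target_identity > 1) stop("target_identity must be in (0, 1]")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  with_seed(seed, {
    s1 <- sample(aa, length, replace = TRUE)
    n_sub <- round((1 - target_identity) * length)
    s2 <- s1
    if (n_sub > 0) {
      pos <- sample.int(length, n_sub)
      s2[pos] <- vapply(s1[pos], function(x) sample(setdiff(aa, x), 1), character(1))
    }
    list(seqs = c(A = paste0(s1, collapse = ""), B = paste0(s2, collapse = "")),
         realized_identity = 1 - n_sub / length)
  })
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  invisible(path)
}
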