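# Rigid-body superposition with iterative outlier pruning, van der Waals
# overlap contacts, and a heavy-atom geometric hydrogen-bond criterion.

as_xyz <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop("coordinates must be an n x 3 matrix")
  storage.mode(m) <- "double"
  m
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD of paired
#' points, moving set B onto set A.
#'
#' @param a,b n x 3 coordinate matrices of paired points (n >= 3,
#'   non-collinear).
#' @return Object of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd_all`, `n_all`, and the transformed B coordinates
#'   `b_fit`.
#' @export
kabsch <- function(a, b) {
  a <- as_xyz(a)
  b <- as_xyz(b)
  if (nrow(a) != nrow(b)) stop("point sets must pair one-to-one")
  if (nrow(a) < 3L) stop("need at least 3 point pairs")
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca)
  b0 <- sweep(b, 2L, cb)
  h <- crossprod(b0, a0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  if (abs(det(h)) < 1e-12 && all(abs(s$d[2:3]) < 1e-9)) {
    stop("degenerate (collinear or coincident) geometry")
  }
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- ca - as.vector(rot %*% cb)
  b_fit <- sweep(b %*% t(rot), 2L, trans, `+`)
  dev <- sqrt(rowSums((a - b_fit)^2))
  structure(list(rotation = rot, translation = trans,
                 rmsd_all = sqrt(mean(dev^2)), n_all = nrow(a),
                 rmsd_pruned = sqrt(mean(dev^2)), n_pruned = nrow(a),
                 retained = seq_len(nrow(a)), b_fit = b_fit,
                 deviations = dev),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> RMSD %.3f A over %d pruned pairs (%.3f A across all %d)\n",
              x$rmsd_pruned, x$n_pruned, x$rmsd_all, x$n_all))
  invisible(x)
}

#' Superposition with iterative outlier pruning
#'
#' Fits on the currently retained pairs, drops pairs whose post-fit
#' deviation exceeds `prune_cutoff`, and refits until stable (or fewer than
#' 3 pairs would remain, in which case the last stable fit is reported with
#' a warning). `rmsd_pruned` is computed over retained pairs and `rmsd_all`
#' over all pairs, both under the final transform.
#'
#' @param a,b n x 3 coordinate matrices of paired points.
#' @param prune_cutoff Deviation cutoff in Angstrom (default 2.0).
#' @param max_iter Iteration cap (default 100).
#' @return A `superposition` object (see [kabsch()]) with `retained`
#'   holding the surviving pair indices.
#' @export
prune_superpose <- function(a, b, prune_cutoff = 2.0, max_iter = 100L) {
  a <- as_xyz(a)
  b <- as_xyz(b)
  keep <- seq_len(nrow(a))
  fit <- kabsch(a, b)
  for (iter in seq_len(max_iter)) {
    sub <- kabsch(a[keep, , drop = FALSE], b[keep, , drop = FALSE])
    b_fit_all <- sweep(b %*% t(sub$rotation), 2L, sub$translation, `+`)
    dev_all <- sqrt(rowSums((a - b_fit_all)^2))
    new_keep <- keep[dev_all[keep] <= prune_cutoff]
    if (length(new_keep) < 3L) {
      warning("pruning collapsed below 3 pairs: reporting last stable fit")
      break
    }
    fit <- sub
    fit$b_fit <- b_fit_all
    fit$deviations <- dev_all
    fit$rmsd_all <- sqrt(mean(dev_all^2))
    fit$n_all <- nrow(a)
    fit$retained <- keep
    fit$rmsd_pruned <- sqrt(mean(dev_all[keep]^2))
    fit$n_pruned <- length(keep)
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  fit
}

element_radius <- function(elements) {
  r <- VDW_RADII[toupper(elements)]
  if (anyNA(r)) {
    stop(sprintf("no van der Waals radius for element(s): %s",
                 paste(unique(elements[is.na(r)]), collapse = ", ")))
  }
  unname(r)
}

resolve_selection <- function(model, sel) {
  n <- nrow(model$atoms)
  idx <- if (is.logical(sel)) which(sel) else as.integer(sel)
  if (length(idx) == 0L || any(idx < 1L | idx > n)) {
    stop("selection must index atoms of the model")
  }
  idx
}

#' Van der Waals overlap contacts between two selections
#'
#' A pair is reported when `overlap = r_a + r_b - d >= overlap_cutoff`
#' (default -0.4 A, i.e. atoms approaching within 0.4 A of van der Waals
#' touching). For nitrogen/oxygen donor-acceptor pairs the overlap is first
#' reduced by `hbond_allowance`. Pairs within the same residue are never
#' reported. Radii come from the fixed table named in the output.
#'
#' @param model A `structure_model` from [read_structure()].
#' @param selection_a,selection_b Disjoint atom selections (indices or
#'   logical vectors over the atom table).
#' @param overlap_cutoff Minimum overlap in Angstrom (default -0.4).
#' @param hbond_allowance Overlap reduction for N/O vs N/O pairs (default 0).
#' @return Object of class `contact_set`: data frame `pairs` (atom_a,
#'   atom_b, distance, overlap) plus the criterion parameters and radii
#'   table name.
#' @export
vdw_contacts <- function(model, selection_a, selection_b,
                         overlap_cutoff = -0.4, hbond_allowance = 0) {
  ia <- resolve_selection(model, selection_a)
  ib <- resolve_selection(model, selection_b)
  if (length(intersect(ia, ib)) > 0L) stop("selections must be disjoint")
  at <- model$atoms
  ra <- element_radius(at$element[ia])
  rb <- element_radius(at$element[ib])
  xa <- as.matrix(at[ia, c("x", "y", "z")])
  xb <- as.matrix(at[ib, c("x", "y", "z")])
  res_a <- paste(at$chain[ia], at$resno[ia], at$resid[ia])
  res_b <- paste(at$chain[ib], at$resno[ib], at$resid[ib])
  no_a <- at$element[ia] %in% c("N", "O")
  no_b <- at$element[ib] %in% c("N", "O")
  out <- vector("list", length(ia))
  for (i in seq_along(ia)) {
    d <- sqrt(colSums((t(xb) - xa[i, ])^2))
    overlap <- ra[i] + rb - d
    eff <- overlap - ifelse(no_a[i] & no_b, hbond_allowance, 0)
    hit <- which(eff >= overlap_cutoff & res_b != res_a[i])
    if (length(hit) > 0L) {
      out[[i]] <- data.frame(atom_a = ia[i], atom_b = ib[hit],
                             distance = d[hit], overlap = overlap[hit])
    }
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(pairs)) {
    pairs <- data.frame(atom_a = integer(0L), atom_b = integer(0L),
                        distance = numeric(0L), overlap = numeric(0L))
  }
  rownames(pairs) <- NULL
  structure(list(pairs = pairs,
                 overlap_cutoff = overlap_cutoff,
                 hbond_allowance = hbond_allowance,
                 radii_table = VDW_TABLE_NAME),
            class = "contact_set")
}

#' @export
print.contact_set <- function(x, ...) {
  cat(sprintf("<contact_set> %d pair(s) at overlap >= %.2f A (radii: %s)\n",
              nrow(x$pairs), x$overlap_cutoff, x$radii_table))
  invisible(x)
}

#' Geometric heavy-atom hydrogen bonds between two selections
#'
#' No hydrogens are placed: a bond is reported when a donor-capable N/O in
#' one selection lies within `d_max` of an acceptor N/O in the other and the
#' angle antecedent-donor-acceptor is at least `angle_min` for some
#' covalently bonded antecedent (heavy atom within 1.9 A in the donor's
#' residue). Donors without any antecedent pass the angle criterion
#' vacuously. Both selection directions are scanned.
#'
#' @param model A `structure_model`.
#' @param selection_a,selection_b Disjoint atom selections.
#' @param d_max Maximum donor-acceptor heavy-atom distance (default 3.5 A).
#' @param angle_min Minimum donor angle in degrees (default 120).
#' @return Data frame: donor, acceptor (atom indices), distance, angle.
#' @export
hbonds <- function(model, selection_a, selection_b, d_max = 3.5,
                   angle_min = 120) {
  ia <- resolve_selection(model, selection_a)
  ib <- resolve_selection(model, selection_b)
  if (length(intersect(ia, ib)) > 0L) stop("selections must be disjoint")
  at <- model$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  is_no <- at$element %in% c("N", "O")
  donor_angle_ok <- function(d_idx, a_idx) {
    same_res <- which(at$chain == at$chain[d_idx] &
                      at$resno == at$resno[d_idx] &
                      at$resid == at$resid[d_idx])
    same_res <- setdiff(same_res, c(d_idx, a_idx))
    if (length(same_res) == 0L) return(c(ok = TRUE, angle = NA_real_))
    dd <- sqrt(rowSums((xyz[same_res, , drop = FALSE] -
                        matrix(xyz[d_idx, ], length(same_res), 3L, byrow = TRUE))^2))
    ante <- same_res[dd < 1.9]
    if (length(ante) == 0L) return(c(ok = TRUE, angle = NA_real_))
    angles <- vapply(ante, function(k) {
      v1 <- xyz[k, ] - xyz[d_idx, ]
      v2 <- xyz[a_idx, ] - xyz[d_idx, ]
      cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }, numeric(1L))
    c(ok = max(angles) >= angle_min, angle = max(angles))
  }
  scan_dir <- function(donors, acceptors) {
    donors <- donors[is_no[donors]]
    acceptors <- acceptors[is_no[acceptors]]
    rows <- list()
    for (d_idx in donors) {
      dist <- sqrt(colSums((t(xyz[acceptors, , drop = FALSE]) - xyz[d_idx, ])^2))
      for (j in which(dist <= d_max)) {
        chk <- donor_angle_ok(d_idx, acceptors[j])
        if (chk[["ok"]] == 1) {
          rows[[length(rows) + 1L]] <- data.frame(
            donor = d_idx, acceptor = acceptors[j],
            distance = dist[j], angle = chk[["angle"]])
        }
      }
    }
    rows
  }
  rows <- c(scan_dir(ia, ib), scan_dir(ib, ia))
  if (length(rows) == 0L) {
    return(data.frame(donor = integer(0L), acceptor = integer(0L),
                      distance = numeric(0L), angle = numeric(0L)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-residue ligand contact table
#'
#' Counts van der Waals contacts from every protein residue to each named
#' ligand (HETATM residue name, e.g. HEM or ASC), under the [vdw_contacts()]
#' criterion.
#'
#' @param model A `structure_model`.
#' @param ligand_names Character vector of ligand residue names.
#' @param overlap_cutoff,hbond_allowance Passed to [vdw_contacts()].
#' @return Data frame sorted by residue number: chain, resno, resid, one
#'   count column per ligand, and `any_contact`.
#' @export
ligand_contact_table <- function(model, ligand_names = c("HEM", "ASC"),
                                 overlap_cutoff = -0.4, hbond_allowance = 0) {
  at <- model$atoms
  prot_idx <- which(!at$het)
  if (length(prot_idx) == 0L) stop("model has no protein (ATOM) records")
  res_key <- paste(at$chain, at$resno, at$resid)
  prot_res <- unique(res_key[prot_idx])
  counts <- matrix(0L, length(prot_res), length(ligand_names),
                   dimnames = list(prot_res, ligand_names))
  for (lig in ligand_names) {
    lig_idx <- which(at$het & at$resid == lig)
    if (length(lig_idx) == 0L) {
      warning(sprintf("ligand '%s' absent from model", lig))
      next
    }
    cs <- vdw_contacts(model, prot_idx, lig_idx,
                       overlap_cutoff = overlap_cutoff,
                       hbond_allowance = hbond_allowance)
    if (nrow(cs$pairs) > 0L) {
      tab <- table(res_key[cs$pairs$atom_a])
      counts[names(tab), lig] <- as.integer(tab)
    }
  }
  first <- match(prot_res, res_key)
  out <- data.frame(chain = at$chain[first], resno = at$resno[first],
                    resid = at$resid[first], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(counts, row.names = NULL))
  out$any_contact <- rowSums(counts) > 0L
  out[order(out$chain, out$resno), , drop = FALSE]
}
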