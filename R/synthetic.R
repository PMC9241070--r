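# Synthetic labelled feature matrices emulating the class-conditional
# structure of annotated zinc sites (site size, ligand count, ligand
# accessibility, Cys/His conservation), plus exact-geometry toy PDB files
# for testing the distance rules.  Distribution families: negative binomial
# for counts, log-normal for accessibilities, Dirichlet with a boost on the
# true residue for conservation rows.

#' Synthetic dataset specification
#'
#' Defaults encode the class-conditional structure of the annotated zinc
#' dataset: physiological sites average 22.3 residues with 3-4 amino-acid
#' ligands of low accessibility and strongly conserved Cys/His; adventitious
#' sites average 12.5 residues with 1-2 more exposed, less conserved
#' ligands.  Second-sphere and background accessibility share one
#' distribution across classes.
#'
#' @param physiological,adventitious Per-class parameter lists; any element
#'   given here overrides the default (see Details in the package
#'   vignette).  Elements: `site_mean` (mean MBS residue count),
#'   `ligand_probs` (named ligand-count distribution), `ligand_sasa_meanlog`
#'   and `ligand_sasa_sdlog` (log-normal ligand accessibility),
#'   `ligand_aa_probs` (ligand residue identity), `conservation_boost` and
#'   `conservation_base` (Dirichlet concentration on/around the true
#'   residue).
#' @param site_size_dispersion Negative-binomial size for the environment
#'   residue count (default 30).
#' @param chain_min,chain_mean,chain_size Chain-length distribution:
#'   `L = chain_min + NB(mean = chain_mean - chain_min, size = chain_size)`,
#'   drawn independently of the site so chain length carries no label
#'   information (defaults 30, 55, 6; L is raised to `site size + 3` in the
#'   rare draws where the site would not fit).
#' @param sasa_cap Physical ceiling on absolute accessibility draws
#'   (default 250 Angstrom^2).
#' @param env_sasa_meanlog,env_sasa_sdlog Shared log-normal accessibility of
#'   non-ligand residues (default meanlog log(20), sdlog 1.4: a wide
#'   distribution with a substantial fraction of deeply buried residues,
#'   as in folded chains).
#' @param background_boost,background_base Dirichlet concentrations for
#'   ordinary non-ligand conservation rows (default 3 and 6).
#' @param conserved_fraction Fraction of non-ligand positions that are
#'   strongly conserved distractors (buried structural or functional
#'   residues unrelated to the site; default 0.35).  Without them the site
#'   residues would be identifiable from conservation alone, which real
#'   chains do not allow.
#' @param conserved_boost Dirichlet boost at conserved distractor positions
#'   (default 18, matching the conservation depth of physiological
#'   ligands).
#' @param conserved_aa_probs Residue-identity profile of conserved
#'   distractor positions (enriched in Cys/His/Asp/Glu/Gly/Trp/Tyr, the
#'   residues that tend to be conserved for structural or catalytic
#'   reasons).
#' @param ss_probs Secondary-structure background frequencies.
#' @param extra_noise_column Append a 30th pure-noise N(0,1) column (test
#'   harness variant; default FALSE).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(physiological = list(), adventitious = list(),
                           site_size_dispersion = 30,
                           chain_min = 30, chain_mean = 55, chain_size = 6,
                           sasa_cap = 250,
                           env_sasa_meanlog = log(20), env_sasa_sdlog = 1.4,
                           background_boost = 3, background_base = 6,
                           conserved_fraction = 0.35, conserved_boost = 18,
                           conserved_aa_probs = c(C = 0.10, H = 0.08,
                                                  D = 0.10, E = 0.08,
                                                  G = 0.12, W = 0.05,
                                                  Y = 0.07, P = 0.06,
                                                  R = 0.06, N = 0.06,
                                                  S = 0.06, T = 0.06,
                                                  L = 0.10),
                           ss_probs = c(helix = 0.35, sheet = 0.25,
                                        turn = 0.15, other = 0.25),
                           extra_noise_column = FALSE) {
  phys_default <- list(
    site_mean = 22.3,
    ligand_probs = c(`2` = 0.05, `3` = 0.40, `4` = 0.40, `5` = 0.12,
                     `6` = 0.03),
    ligand_sasa_meanlog = log(10), ligand_sasa_sdlog = 1.0,
    ligand_aa_probs = c(C = 0.50, H = 0.40, D = 0.04, E = 0.03, N = 0.03),
    conservation_boost = 18, conservation_base = 2)
  adv_default <- list(
    site_mean = 12.5,
    ligand_probs = c(`1` = 0.50, `2` = 0.35, `3` = 0.12, `4` = 0.03),
    ligand_sasa_meanlog = log(25), ligand_sasa_sdlog = 0.8,
    ligand_aa_probs = c(C = 0.30, H = 0.35, D = 0.15, E = 0.10, N = 0.05,
                        S = 0.05),
    conservation_boost = 5, conservation_base = 5)
  merge_class <- function(def, user) {
    def[names(user)] <- user
    stopifnot(def$site_mean > 0,
              abs(sum(def$ligand_probs) - 1) < 1e-9,
              abs(sum(def$ligand_aa_probs) - 1) < 1e-9,
              def$conservation_boost >= 0, def$conservation_base > 0)
    def
  }
  stopifnot(abs(sum(ss_probs) - 1) < 1e-9, all(ss_probs >= 0),
            conserved_fraction >= 0, conserved_fraction <= 1,
            abs(sum(conserved_aa_probs) - 1) < 1e-9)
  structure(list(
    physiological = merge_class(phys_default, physiological),
    adventitious = merge_class(adv_default, adventitious),
    site_size_dispersion = site_size_dispersion,
    chain_min = chain_min, chain_mean = chain_mean,
    chain_size = chain_size, sasa_cap = sasa_cap,
    env_sasa_meanlog = env_sasa_meanlog, env_sasa_sdlog = env_sasa_sdlog,
    background_boost = background_boost, background_base = background_base,
    conserved_fraction = conserved_fraction,
    conserved_boost = conserved_boost,
    conserved_aa_probs = conserved_aa_probs,
    ss_probs = ss_probs,
    extra_noise_column = extra_noise_column), class = "synthetic_spec")
}

#' Equalise the class-conditional parameters of a spec
#'
#' Returns a spec whose two classes share the averaged parameters — a null
#' generator under which no feature carries label information, so a trained
#' classifier should sit at chance.
#'
#' @param spec A `synthetic_spec`.
#' @return A `synthetic_spec` with identical class parameters.
#' @export
equalize_classes <- function(spec) {
  avg_probs <- function(a, b) {
    keys <- sort(unique(c(names(a), names(b))))
    av <- (ifelse(is.na(a[keys]), 0, a[keys]) +
           ifelse(is.na(b[keys]), 0, b[keys])) / 2
    setNames(av / sum(av), keys)
  }
  p <- spec$physiological; a <- spec$adventitious
  shared <- list(
    site_mean = (p$site_mean + a$site_mean) / 2,
    ligand_probs = avg_probs(p$ligand_probs, a$ligand_probs),
    ligand_sasa_meanlog = (p$ligand_sasa_meanlog + a$ligand_sasa_meanlog) / 2,
    ligand_sasa_sdlog = (p$ligand_sasa_sdlog + a$ligand_sasa_sdlog) / 2,
    ligand_aa_probs = avg_probs(p$ligand_aa_probs, a$ligand_aa_probs),
    conservation_boost = (p$conservation_boost + a$conservation_boost) / 2,
    conservation_base = (p$conservation_base + a$conservation_base) / 2)
  spec$physiological <- shared
  spec$adventitious <- shared
  spec
}

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate one synthetic site
#'
#' @param label `"physiological"` or `"adventitious"`.
#' @param spec A [synthetic_spec()].
#' @param site_id Site identifier.
#' @return A `site_features` object (consumes the current R RNG stream).
#' @export
generate_site <- function(label, spec = synthetic_spec(),
                          site_id = "synthetic") {
  label <- match.arg(label, c("physiological", "adventitious"))
  cls <- spec[[label]]
  lig_k <- as.integer(names(cls$ligand_probs))
  lig_n <- sample(lig_k, 1, prob = cls$ligand_probs)
  env_mean <- cls$site_mean - sum(lig_k * cls$ligand_probs)
  stopifnot(env_mean > 0)
  env_n <- rnbinom(1, size = spec$site_size_dispersion, mu = env_mean)
  site_n <- lig_n + env_n
  L <- spec$chain_min + rnbinom(1, size = spec$chain_size,
                                mu = spec$chain_mean - spec$chain_min)
  L <- max(L, site_n + 3L)
  pos <- sample(L, site_n)
  lig_pos <- pos[seq_len(lig_n)]
  env_pos <- setdiff(pos, lig_pos)
  roles <- integer(L)
  roles[lig_pos] <- 2L
  roles[env_pos] <- 1L

  aa <- character(L)
  is_lig <- roles == 2L
  # conserved distractor positions among the non-ligand residues
  is_cons <- !is_lig & runif(L) < spec$conserved_fraction
  aa[is_lig] <- sample(names(cls$ligand_aa_probs), sum(is_lig),
                       replace = TRUE, prob = cls$ligand_aa_probs)
  aa[is_cons] <- sample(names(spec$conserved_aa_probs), sum(is_cons),
                        replace = TRUE, prob = spec$conserved_aa_probs)
  plain <- !is_lig & !is_cons
  aa[plain] <- sample(.AA, sum(plain), replace = TRUE,
                      prob = .AA_BACKGROUND)

  v <- matrix(0, L, 29, dimnames = list(NULL, feature_names()))
  for (t in seq_len(L)) {
    boost <- if (is_lig[t]) cls$conservation_boost
             else if (is_cons[t]) spec$conserved_boost
             else spec$background_boost
    base <- if (is_lig[t]) cls$conservation_base else spec$background_base
    alpha <- base * .AA_BACKGROUND + boost * (names(.AA_BACKGROUND) == aa[t])
    v[t, .COL_FREQ] <- .rdirichlet1(alpha)
  }
  abs_sasa <- numeric(L)
  abs_sasa[is_lig] <- rlnorm(sum(is_lig), cls$ligand_sasa_meanlog,
                             cls$ligand_sasa_sdlog)
  abs_sasa[!is_lig] <- rlnorm(sum(!is_lig), spec$env_sasa_meanlog,
                              spec$env_sasa_sdlog)
  abs_sasa <- pmin(abs_sasa, spec$sasa_cap)
  ref <- max_sasa_reference()[bio3d::aa123(aa)]
  v[, .COL_ABS] <- abs_sasa
  v[, .COL_REL] <- 100 * abs_sasa / unname(ref)
  v[cbind(seq_len(L), .COL_ROLE[match(roles, c(2, 1, 0))])] <- 1
  ss <- sample(names(spec$ss_probs), L, replace = TRUE,
               prob = spec$ss_probs)
  v[cbind(seq_len(L), .COL_SS[match(ss, .SS_CLASSES)])] <- 1
  if (spec$extra_noise_column) {
    v <- cbind(v, noise = rnorm(L))
    out <- structure(list(site_id = site_id, values = v, label = label,
                          chain = "A", positions = NULL, sequence = aa),
                     class = "site_features")
    return(out)
  }
  site_features(v, label = label, site_id = site_id, chain = "A",
                sequence = aa)
}

#' Generate a labelled synthetic dataset
#'
#' Deterministic under `seed`; the generation manifest (spec and seed) is
#' stored so the dataset can be regenerated exactly.
#'
#' @param n_physiological,n_adventitious Sites per class.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return A `site_dataset`.
#' @export
generate_dataset <- function(n_physiological, n_adventitious,
                             spec = synthetic_spec(), seed = 1) {
  stopifnot(n_physiological >= 1, n_adventitious >= 1)
  set.seed(seed)
  labels <- c(rep("physiological", n_physiological),
              rep("adventitious", n_adventitious))
  sites <- lapply(seq_along(labels), function(i)
    generate_site(labels[i], spec,
                  site_id = sprintf("syn_%s_%04d", substr(labels[i], 1, 4), i)))
  site_dataset(sites, manifest = list(seed = seed,
                                      n_physiological = n_physiological,
                                      n_adventitious = n_adventitious,
                                      spec = unclass(spec)))
}

# --- toy structures with exact geometry -----------------------------------

#' Write an atom table as minimal PDB text
#'
#' Emits standard-conforming ATOM/HETATM/TER/END records (fixed-width
#' columns, 3-decimal coordinates) so both this package and third-party
#' parsers can read the file.
#'
#' @param atoms Data frame with columns `name`, `element`, `resid`,
#'   `chain`, `resno`, `x`, `y`, `z`, `is_hetero` (optional `occupancy`).
#' @param path Optional output file.
#' @return Character vector of PDB lines (invisibly when written).
#' @export
write_pdb <- function(atoms, path = NULL) {
  occ <- if (is.null(atoms$occupancy)) rep(1, nrow(atoms)) else atoms$occupancy
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    nm <- atoms$name[i]
    nm_fmt <- if (nchar(atoms$element[i]) >= 2 || nchar(nm) >= 4)
      sprintf("%-4s", nm) else sprintf(" %-3s", nm)
    sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            if (isTRUE(atoms$is_hetero[i])) "HETATM" else "ATOM", i,
            nm_fmt, "", atoms$resid[i], atoms$chain[i], atoms$resno[i], "",
            atoms$x[i], atoms$y[i], atoms$z[i], occ[i], 0,
            toupper(atoms$element[i]))
  }, character(1))
  lines <- c(lines, "END")
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

#' Generate a toy structure with exact metal-atom distances
#'
#' Places a metal HETATM at the origin and each requested atom at its exact
#' distance along the given (or an automatically spread) direction.
#' Coordinates survive the PDB fixed-width round trip to within 1e-3 A.
#'
#' @param geometry Data frame with columns `element`, `name`, `resid`,
#'   `resno`, `distance`, optionally `chain` (default "A"), `is_hetero`
#'   (default FALSE) and direction columns `dx`, `dy`, `dz`.
#' @param metal_element Metal element symbol (default "ZN").
#' @param path Optional output PDB path.
#' @return PDB text lines (invisibly when written to `path`).
#' @export
generate_toy_structure <- function(geometry, metal_element = "ZN",
                                   path = NULL) {
  stopifnot(all(geometry$distance > 0))
  n <- nrow(geometry)
  if (is.null(geometry$chain)) geometry$chain <- "A"
  if (is.null(geometry$is_hetero)) geometry$is_hetero <- FALSE
  if (is.null(geometry$dx)) {
    # spread directions over a golden spiral so atoms do not collide
    i <- seq_len(n)
    yv <- 1 - 2 * (i - 0.5) / n
    rv <- sqrt(pmax(0, 1 - yv^2))
    th <- pi * (3 - sqrt(5)) * i
    geometry$dx <- cos(th) * rv
    geometry$dy <- yv
    geometry$dz <- sin(th) * rv
  }
  len <- sqrt(geometry$dx^2 + geometry$dy^2 + geometry$dz^2)
  coords <- round(cbind(geometry$dx, geometry$dy, geometry$dz) / len *
                    geometry$distance, 3)
  all_xyz <- rbind(c(0, 0, 0), coords)
  dmin <- min(stats::dist(all_xyz))
  if (dmin < 0.5)
    stop(sprintf("overlapping atoms: minimum pairwise distance %.3f A", dmin))
  atoms <- data.frame(
    name = c(toupper(metal_element), geometry$name),
    element = c(toupper(metal_element), geometry$element),
    resid = c(toupper(metal_element), geometry$resid),
    chain = c("A", geometry$chain),
    resno = c(999L, geometry$resno),
    x = all_xyz[, 1], y = all_xyz[, 2], z = all_xyz[, 3],
    is_hetero = c(TRUE, geometry$is_hetero),
    stringsAsFactors = FALSE)
  write_pdb(atoms, path)
}
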