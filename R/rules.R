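# Interpretable rule-based reference classifier: large sites and sites with
# many protein-provided ligands are extremely likely to be physiological.

#' Rule-baseline configuration
#'
#' @param min_site_residues Site-size clause: physiological when the MBS
#'   involves at least this many protein residues (default 20, inclusive).
#' @param min_protein_ligands Ligand-count clause: physiological when at
#'   least this many amino acids bind the metal (default 4, inclusive).
#' @param ligand_sasa_cutoff Optional accessibility clause (Angstrom^2):
#'   physiological when the mean absolute SASA of the metal ligands is below
#'   the cutoff.  Unset by default — the accessibility distributions overlap
#'   too much for a reliable cutoff.
#' @return Object of class `rule_config`.
#' @export
rule_config <- function(min_site_residues = 20, min_protein_ligands = 4,
                        ligand_sasa_cutoff = NULL) {
  stopifnot(min_site_residues >= 1, min_protein_ligands >= 1,
            is.null(ligand_sasa_cutoff) || ligand_sasa_cutoff >= 0)
  structure(list(min_site_residues = min_site_residues,
                 min_protein_ligands = min_protein_ligands,
                 ligand_sasa_cutoff = ligand_sasa_cutoff),
            class = "rule_config")
}

#' Rule inputs from a site's feature matrix
#'
#' Counts amino-acid ligands (role-ligand rows), averages the absolute
#' accessibility over ligand rows (first sphere) and environment rows
#' (second sphere), and flags a possible purification-tag artifact when
#' more than two ligands are His residues inside a terminal 12-residue
#' window of the chain.
#'
#' @param features A `site_features` object.
#' @param site Optional `metal_site`; when given, its stored counts are
#'   used (they also include ligands from other chains).
#' @return List with `site_residue_count`, `protein_ligand_count`,
#'   `mean_ligand_sasa`, `mean_second_sphere_sasa`, `polyhis_suspect`.
#' @export
site_summary <- function(features, site = NULL) {
  v <- features$values
  lig <- v[, "role_ligand"] == 1
  env <- v[, "role_env"] == 1
  if (!any(lig)) stop("site has no ligand rows in chain ", features$chain)
  polyhis <- FALSE
  if (!is.null(features$sequence)) {
    L <- nrow(v)
    terminal <- seq_len(L) <= 12 | seq_len(L) > L - 12
    his_lig <- lig & features$sequence == "H" & terminal
    polyhis <- sum(his_lig) > 2
  }
  list(site_residue_count = if (!is.null(site)) site$site_residue_count
                            else sum(lig) + sum(env),
       protein_ligand_count = if (!is.null(site)) site$protein_ligand_count
                              else sum(lig),
       mean_ligand_sasa = mean(v[lig, "abs_sasa"]),
       mean_second_sphere_sasa = if (any(env)) mean(v[env, "abs_sasa"])
                                 else NA_real_,
       polyhis_suspect = polyhis)
}

#' Rule-based site classification
#'
#' A site is called physiological when any clause fires: the MBS has at
#' least `min_site_residues` protein residues, OR the protein chain
#' provides at least `min_protein_ligands` amino-acid ligands, OR (when a
#' cutoff is configured) the mean ligand accessibility is below it.  Both
#' count thresholds are inclusive.  A possible poly-His purification tag
#' triggers a warning but never changes the classification.
#'
#' @param summaries A single summary from [site_summary()], a list of
#'   summaries, or a data frame with columns `site_residue_count`,
#'   `protein_ligand_count`, and optionally `mean_ligand_sasa` and
#'   `polyhis_suspect`.
#' @param config A [rule_config()].
#' @return Data frame with `class` and the fired-rule trace columns
#'   `size_rule`, `ligand_rule`, `sasa_rule`.
#' @export
rule_classify <- function(summaries, config = rule_config()) {
  if (!is.data.frame(summaries)) {
    if (!is.null(summaries$site_residue_count)) summaries <- list(summaries)
    summaries <- do.call(rbind, lapply(summaries, function(s)
      data.frame(site_residue_count = s$site_residue_count,
                 protein_ligand_count = s$protein_ligand_count,
                 mean_ligand_sasa = if (is.null(s$mean_ligand_sasa))
                   NA_real_ else s$mean_ligand_sasa,
                 polyhis_suspect = isTRUE(s$polyhis_suspect))))
  }
  stopifnot(all(summaries$site_residue_count >= 0),
            all(summaries$protein_ligand_count >= 0))
  size_rule <- summaries$site_residue_count >= config$min_site_residues
  ligand_rule <- summaries$protein_ligand_count >= config$min_protein_ligands
  sasa_rule <- if (is.null(config$ligand_sasa_cutoff))
    rep(FALSE, nrow(summaries))
  else !is.na(summaries$mean_ligand_sasa) &
    summaries$mean_ligand_sasa < config$ligand_sasa_cutoff
  if (!is.null(summaries$polyhis_suspect) && any(summaries$polyhis_suspect))
    warning("possible poly-His purification tag: >2 His ligands in a ",
            "terminal 12-residue window for ",
            sum(summaries$polyhis_suspect), " site(s)")
  data.frame(class = ifelse(size_rule | ligand_rule | sasa_rule,
                            "physiological", "adventitious"),
             size_rule = size_rule, ligand_rule = ligand_rule,
             sasa_rule = sasa_rule, stringsAsFactors = FALSE)
}
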