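#' Default relation vocabulary of the phosphorylation knowledge graph
#'
#' The 32 relation names used by the shipped knowledge-graph schema:
#' protein annotation links (pathways, complexes, GO terms, tissues,
#' cellular components), kinase classification links (domains, families,
#' superfamilies and their hierarchies), isoform resolution, the two
#' kinase/motif links (`k_specific_motif`, `has_motif`) and the nine
#' positional residue relations `residue_1` ... `residue_9` that decompose a
#' 9-mer phosphosite motif into its amino-acid nodes.
#'
#' @return Character vector of 32 relation names.
#' @export
ksmo_relations <- function() {
  c(
    "participating_pathway",
    "part_of_complex",
    "pathway_event_of",
    "bio_process",
    "regulates",
    "positively_regulates",
    "negatively_regulates",
    "mol_func",
    "capable_of",
    "capable_of_part_of",
    "cellular_comp",
    "occurs_in",
    "part_of",
    "expressed_in",
    "is_a",
    "has_domain",
    "belongs_to_family",
    "homologous_superfamily",
    "is_a(domain)",
    "is_a(family)",
    "is_a(form)",
    "k_specific_motif",
    "has_motif",
    paste0("residue_", 1:9)
  )
}

#' The nine positional residue relations
#' @return Character vector `residue_1` ... `residue_9`.
#' @keywords internal
residue_relations <- function() paste0("residue_", 1:9)
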