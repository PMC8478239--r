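#' Structural properties and assay outcomes of seven Gaucher variants
#'
#' The worked-example table for glucocerebrosidase (Gaucher disease):
#' seven missense variants with their externally computed stability change
#' (`ddg`, kcal/mol, EvoEF), ligand contact, contact count,
#' catalytic-domain membership and inverse-parallel relation count, plus
#' the cell-assay responsiveness label and the chaperone assayed
#' (N-nonyl-deoxynojirimycin for the first three variants, Ambroxol for the
#' last four). These rows are the canonical inputs for [predictTreeBatch()].
#'
#' @return data.frame with columns `variant`, `ddg`, `binds_ligand`,
#'   `n_contacts`, `catalytic_domain`, `p_inv`, `responsive`,
#'   `label_source`.
#' @examples
#' predictTreeBatch(gaucherVariants())
#' @export
gaucherVariants <- function() {
  data.frame(
    variant = c("N370S", "L444P", "G202R", "F213I", "R120W", "N188S",
                "D409H"),
    ddg = c(0.28, 1.96, -1.00, 1.05, 2.18, 0.42, 0.55),
    binds_ligand = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    n_contacts = c(3L, 2L, 2L, 5L, 10L, 2L, 2L),
    catalytic_domain = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    p_inv = c(183L, 43L, 219L, 219L, 145L, 208L, 79L),
    responsive = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE),
    label_source = c(rep("N-nonyl-deoxynojirimycin", 3),
                     rep("Ambroxol", 4)))
}
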