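# Deterministic synthetic data. Every stage of the workflow is testable
# offline: compound sets with a planted structure-activity signal
# (activity is a linear function of the hydrogen-bond-donor count plus
# Gaussian noise -- the same descriptor family the real dataset's models
# ended up using), and easy/hard molecule corpora for training the
# fragment scorer. The pools are version-pinned in this file so fixtures
# are byte-stable across releases; they are plumbing for code paths and
# planted statistics, not chemically meaningful antioxidants.

# Indole-like molecules plus simple decoys, spanning 0-3 hydrogen-bond
# donors.
fixture_pool <- function() {
  c(indole = "c1ccc2c(c1)cc[nH]2",
    skatole = "Cc1c[nH]c2ccccc12",
    tryptamine = "NCCc1c[nH]c2ccccc12",
    serotonin = "NCCc1c[nH]c2ccc(O)cc12",
    melatonin = "CC(=O)NCCc1c[nH]c2ccc(OC)cc12",
    indole_carbinol = "OCc1c[nH]c2ccccc12",
    indole_acetic = "OC(=O)Cc1c[nH]c2ccccc12",
    tryptophan = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
    n_methylindole = "Cn1ccc2ccccc21",
    ethylindole = "CCc1c[nH]c2ccccc12",
    methoxyindole = "COc1ccc2[nH]ccc2c1",
    hydroxyindole = "Oc1ccc2[nH]ccc2c1",
    chloroindole = "Clc1ccc2[nH]ccc2c1",
    bromoindole = "Brc1ccc2[nH]ccc2c1",
    fluoroindole = "Fc1ccc2[nH]ccc2c1",
    indole_carboxylic = "OC(=O)c1c[nH]c2ccccc12",
    indole_aldehyde = "O=Cc1c[nH]c2ccccc12",
    amt = "CC(N)Cc1c[nH]c2ccccc12",
    tryptophol = "OCCc1c[nH]c2ccccc12",
    cyanoindole = "N#Cc1c[nH]c2ccccc12",
    dmt = "CN(C)CCc1c[nH]c2ccccc12",
    acetylindole = "CC(=O)c1c[nH]c2ccccc12",
    carbazole = "c1ccc2c(c1)[nH]c1ccccc12",
    indoline = "C1Cc2ccccc2N1",
    oxindole = "O=C1Nc2ccccc2C1",
    indole_acetamide = "NC(=O)Cc1c[nH]c2ccccc12",
    indole_diol = "OCC(O)Cc1c[nH]c2ccccc12",
    methoxytryptamine = "NCCc1c[nH]c2ccc(OC)cc12",
    dimethylindole = "Cc1[nH]c2ccccc2c1C",
    indole_propionic = "OC(=O)CCc1c[nH]c2ccccc12",
    benzene = "c1ccccc1",
    phenol = "Oc1ccccc1",
    catechol = "Oc1ccccc1O",
    aniline = "Nc1ccccc1",
    pyridine = "c1ccncc1",
    furan = "c1ccoc1",
    thiophene = "c1ccsc1",
    ethanol = "CCO",
    acetic_acid = "CC(=O)O",
    cymene = "CC(C)Cc1ccc(C)cc1",
    anisole = "COc1ccccc1",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    glycerol = "OCC(O)CO",
    ethanolamine = "NCCO",
    salicylic = "OC(=O)c1ccccc1O",
    toluene = "Cc1ccccc1",
    benzaldehyde = "O=Cc1ccccc1",
    benzamide = "NC(=O)c1ccccc1",
    benzyl_alcohol = "OCc1ccccc1",
    methylbenzamide = "CNC(=O)c1ccccc1")
}

#' Fixture specification
#'
#' Describes a synthetic seed set: `n_compounds` molecules drawn from the
#' built-in pool, with activity assigned by the rule
#' `activity = a * donor_count + b + Normal(0, sigma)`, clipped to
#' `[0, 100]`. `skew = TRUE` applies a monotone square-root warp towards
#' high activities afterwards, emulating datasets dominated by highly
#' active compounds (a known failure mode for models trained on them).
#'
#' @param n_compounds number of molecules (>= 6, at most the pool size).
#' @param seed integer seed; the same spec yields an identical fixture.
#' @param a,b,sigma activity rule parameters (percent units); defaults
#'   10, 30, 5 give activities spanning roughly 30-70%.
#' @param skew logical, see above.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_compounds = 44L, seed = 1L, a = 10, b = 30,
                         sigma = 5, skew = FALSE) {
  stopifnot(n_compounds >= 6L, sigma >= 0)
  structure(list(n_compounds = as.integer(n_compounds),
                 seed = as.integer(seed), activity_rule = "donor_linear",
                 a = a, b = b, sigma = sigma, skew = isTRUE(skew)),
            class = "fixture_spec")
}

#' Generate a synthetic seed compound set
#'
#' @param spec a [fixture_spec()].
#' @return a [compound_set()] with activities assigned by the spec's
#'   rule; deterministic per seed.
#' @examples
#' \donttest{
#' make_compound_set(fixture_spec(n_compounds = 10, seed = 1))
#' }
#' @export
make_compound_set <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  pool <- fixture_pool()
  if (spec$n_compounds > length(pool))
    stop("n_compounds (", spec$n_compounds, ") exceeds the fixture pool (",
         length(pool), ")")
  pick <- with_seed(spec$seed,
                    sample.int(length(pool), spec$n_compounds))
  smiles <- unname(pool[pick])
  ids <- names(pool)[pick]
  donors <- ob_properties(smiles)$HBD
  noise <- with_seed(spec$seed + 7919L,
                     stats::rnorm(spec$n_compounds, sd = spec$sigma))
  if (spec$sigma == 0) noise[] <- 0
  act <- spec$a * donors + spec$b + noise
  act <- pmin(pmax(act, 0), 100)
  if (spec$skew) act <- 100 * sqrt(act / 100)
  compound_set(smiles, id = ids, activity_pct = act)
}

#' Easy/hard molecule corpora for the fragment scorer
#'
#' Positives are small common ring systems and chains; negatives carry
#' planted rare fragments (perhalogenated strained rings, S-S and N-N
#' motifs, polyynes) absent from the positive set. The two classes are
#' disjoint by canonical SMILES.
#'
#' @param seed integer seed (controls the deterministic shuffle, so
#'   train/held-out partitions differ across seeds).
#' @return list with `positives` and `negatives`, both [compound_set()]s.
#' @export
make_fragment_corpus <- function(seed = 1L) {
  positives <- c("c1ccccc1", "Oc1ccccc1", "c1ccncc1", "C1CCCCC1",
                 "CCO", "CC(=O)O", "Cc1ccccc1", "Nc1ccccc1",
                 "c1ccoc1", "c1ccsc1", "c1ccc2c(c1)cc[nH]2",
                 "c1cc[nH]c1", "c1ccc2ccccc2c1", "CC(=O)NC",
                 "CCOC(C)=O", "CCNCC", "OCCO", "CC(C)O",
                 "CC(=O)c1ccccc1", "COc1ccccc1")
  negatives <- c("FC1(F)C(F)(F)C1(F)F", "C1SS1", "N1NN1",
                 "CP(C)(C)=O", "IC(I)I", "BrC(Br)(Br)Br",
                 "ClC1(Cl)C(Cl)(Cl)C1(Cl)Cl", "S=C=S",
                 "C#CC#CC#C", "N#CC(C#N)C#N", "OB(O)B(O)O",
                 "FC(F)(F)C(F)(F)C(F)(F)F", "CSSSC", "NNNN",
                 "P1PP1", "C1(I)(I)CC1(I)I")
  shuf <- function(x, off) with_seed(seed + off, sample(x))
  pos <- shuf(positives, 0L); neg <- shuf(negatives, 1L)
  list(positives = compound_set(pos, id = paste0("easy_",
                                                 seq_along(pos))),
       negatives = compound_set(neg, id = paste0("hard_",
                                                 seq_along(neg))))
}
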