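#' Curated GT3 grape-cell network reconstruction
#'
#' Builds the stoichiometric network of heterotrophic metabolism of the GT3
#' *Vitis vinifera* cv. Gamay Teinturier cell suspension: glycolysis, TCA
#' cycle, oxidative and non-oxidative pentose phosphate pathway, starch and
#' sucrose metabolism, nitrate assimilation (NR, GS, GOGAT), the shikimate /
#' phenylpropanoid / flavonoid route to the four measured phenolic classes
#' (anthocyanins, flavonols, tannins, stilbenes), overall biosynthesis of
#' proteins, cell wall, lipids (DAG) and nucleotides, simple accumulation of
#' malate, soluble sugars and four free amino acids, oxidative
#' phosphorylation (`Vnrj1`/`Vnrj2`), adenylate kinase (`Vadk`) and
#' non-growth-associated ATP maintenance (`Vnga-ATPm`).
#'
#' Design notes:
#' * The model describes one average cell; compartment tags are annotation
#'   only and every species is a single pooled quantity.
#' * All cofactors (ATP/ADP/AMP, NAD(H), NADP(H), FAD(H2)) are internal,
#'   hence balanced: energy and redox status constrain carbon flux.
#' * Ammonium uptake is omitted (negligible nitrogen source at 2 mM in this
#'   medium); all nitrogen enters as nitrate via `Vno3-up`.
#' * Three reversible steps carry the flavonoid core (`Vnar` naringenin,
#'   `Vdhq` dihydroquercetin, `Vlcc` leucocyanidin); `Vpal` and `Vcoum` are
#'   irreversible and connect the phenolic branch to central metabolism only
#'   through phenylalanine.
#' * The 2-oxoglutarate-dependent dioxygenase steps (`Vdhq`, `Vflav`,
#'   `Vanthoc`) consume 2-oxoglutarate and release succinate.
#' * Exactly 33 internal reactions are irreversible
#'   ([count_irreversible_internal()]).
#'
#' @param p_o_nadh ATP per NADH oxidised in `Vnrj1` (default 2.5, textbook
#'   P/O ratio).
#' @param p_o_fadh2 ATP per FADH2 oxidised in `Vnrj2` (default 1.5).
#' @param protein_composition named numeric vector of amino-acid mole
#'   fractions over `glu`, `gln`, `asp`, `ala`, `phe` used by `Vprotein`;
#'   default equal-molar. Must sum to 1.
#' @param protein_atp ATP cost per peptide bond in `Vprotein` (default 4.3).
#' @return a validated `vf_network`.
#' @export
build_gt3_network <- function(p_o_nadh = 2.5, p_o_fadh2 = 1.5,
                              protein_composition = NULL,
                              protein_atp = 4.3) {
  if (is.null(protein_composition)) {
    protein_composition <- c(glu = 0.2, gln = 0.2, asp = 0.2, ala = 0.2, phe = 0.2)
  }
  aa <- c("glu", "gln", "asp", "ala", "phe")
  if (!setequal(names(protein_composition), aa))
    vf_stop("protein_composition must be named over: %s", paste(aa, collapse = ", "))
  if (abs(sum(protein_composition) - 1) > 1e-9)
    vf_stop("protein_composition must sum to 1")
  if (p_o_nadh <= 0 || p_o_fadh2 <= 0) vf_stop("P/O ratios must be positive")
  pc <- protein_composition[aa]

  m <- function(id, name, comp = "cytosol") metabolite(id, name, "internal", comp)
  cof <- function(id, name, comp = "cytosol")
    metabolite(id, name, "internal", comp, cofactor = TRUE)
  ext <- function(id, name, comp) metabolite(id, name, "external", comp)

  mets <- list(
    # -- sugars and phosphorylated intermediates
    m("glc", "glucose"), m("fru", "fructose"), m("suc", "sucrose"),
    m("g6p", "glucose 6-phosphate"), m("f6p", "fructose 6-phosphate"),
    m("fbp", "fructose 1,6-bisphosphate"),
    m("gap", "glyceraldehyde 3-phosphate (triose phosphate pool)"),
    m("pg3", "3-phosphoglycerate"), m("pep", "phosphoenolpyruvate"),
    m("pyr", "pyruvate"),
    m("starch", "starch (glucan unit)", "plastid"),
    m("pg6", "6-phosphogluconate"), m("ru5p", "ribulose 5-phosphate"),
    m("r5p", "ribose 5-phosphate"), m("x5p", "xylulose 5-phosphate"),
    m("s7p", "sedoheptulose 7-phosphate"), m("e4p", "erythrose 4-phosphate"),
    # -- organic acids / TCA
    m("accoa", "acetyl-CoA"), m("cit", "citrate", "mitochondrion"),
    m("akg", "2-oxoglutarate", "mitochondrion"),
    m("succ", "succinate", "mitochondrion"), m("fum", "fumarate", "mitochondrion"),
    m("mal", "malate"), m("oaa", "oxaloacetate"),
    # -- nitrogen
    m("no3", "nitrate"), m("no2", "nitrite"), m("nh4", "ammonium"),
    m("glu", "glutamate"), m("gln", "glutamine"), m("asp", "aspartate"),
    m("ala", "alanine"), m("phe", "phenylalanine"),
    # -- aromatic / phenylpropanoid / flavonoid
    m("chor", "chorismate", "plastid"), m("cin", "trans-cinnamate"),
    m("coumcoa", "4-coumaroyl-CoA"), m("malcoa", "malonyl-CoA"),
    m("chal", "naringenin chalcone"), m("nar", "naringenin"),
    m("dhq", "dihydroquercetin"), m("lcc", "leucocyanidin"),
    # -- inorganic and cofactors
    m("co2", "carbon dioxide"), m("pi", "inorganic phosphate"),
    m("ppi", "pyrophosphate"),
    m("coa", "coenzyme A"),
    cof("atp", "ATP"), cof("adp", "ADP"), cof("amp", "AMP"),
    cof("nad", "NAD+", "mitochondrion"), cof("nadh", "NADH", "mitochondrion"),
    cof("nadp", "NADP+"), cof("nadph", "NADPH"),
    cof("fad", "FAD", "mitochondrion"), cof("fadh2", "FADH2", "mitochondrion"),
    # -- external: medium
    ext("glc_e", "glucose (medium)", "medium"),
    ext("fru_e", "fructose (medium)", "medium"),
    ext("no3_e", "nitrate (medium)", "medium"),
    ext("pi_e", "phosphate (medium)", "medium"),
    ext("co2_e", "carbon dioxide (off-gas)", "medium"),
    # -- external: vacuolar accumulation pools
    ext("mal_v", "accumulated malate", "vacuole"),
    ext("glc_v", "accumulated glucose", "vacuole"),
    ext("fru_v", "accumulated fructose", "vacuole"),
    ext("suc_v", "accumulated sucrose", "vacuole"),
    ext("glu_v", "accumulated glutamate", "vacuole"),
    ext("asp_v", "accumulated aspartate", "vacuole"),
    ext("ala_v", "accumulated alanine", "vacuole"),
    ext("phe_v", "accumulated phenylalanine", "vacuole"),
    # -- external: biomass and phenolic products
    ext("anthoc_b", "anthocyanins", "vacuole"),
    ext("flavonol_b", "flavonols", "vacuole"),
    ext("tannin_b", "condensed tannins (flavan-3-ol unit)", "vacuole"),
    ext("stilb_b", "stilbenes (resveratrol)", "vacuole"),
    ext("cw_b", "cell wall polysaccharide (hexose unit)", "wall"),
    ext("protein_b", "protein (residue unit)", "biomass"),
    ext("dag_b", "diacylglycerol", "biomass"),
    ext("nucl_b", "nucleotides (RNA+DNA, nucleotide unit)", "biomass")
  )

  rx <- function(id, s, rev = FALSE, kind = "internal", name = id)
    reaction(id, s, reversible = rev, kind = kind, name = name)

  y1 <- p_o_nadh; y2 <- p_o_fadh2
  reactions <- list(
    # ---- uptake and gas/phosphate exchange
    rx("Vglc-up", c(glc_e = -1, glc = 1), kind = "exchange", name = "glucose uptake"),
    rx("Vfru-up", c(fru_e = -1, fru = 1), kind = "exchange", name = "fructose uptake"),
    rx("Vno3-up", c(no3_e = -1, no3 = 1), kind = "exchange", name = "nitrate uptake"),
    rx("Vpi-up", c(pi_e = -1, pi = 1), kind = "exchange", name = "phosphate uptake"),
    rx("Vco2-out", c(co2 = -1, co2_e = 1), kind = "exchange", name = "CO2 evolution"),
    # ---- sucrose / starch metabolism
    rx("Vhk", c(glc = -1, atp = -1, g6p = 1, adp = 1), name = "hexokinase"),
    rx("Vfk", c(fru = -1, atp = -1, f6p = 1, adp = 1), name = "fructokinase"),
    rx("Vpgi", c(g6p = -1, f6p = 1), rev = TRUE, name = "phosphoglucose isomerase"),
    rx("Vsps", c(f6p = -1, g6p = -1, atp = -1, suc = 1, adp = 1, pi = 1, ppi = 1),
       name = "sucrose synthesis (UGPase+SPS+SPP lump)"),
    rx("Vinv", c(suc = -1, glc = 1, fru = 1), name = "invertase"),
    rx("Vstarch-syn", c(g6p = -1, atp = -1, starch = 1, adp = 1, pi = 2),
       name = "starch synthesis (AGPase+SS lump)"),
    rx("Vstarch-deg", c(starch = -1, pi = -1, g6p = 1),
       name = "starch phosphorolysis"),
    rx("Vppase", c(ppi = -1, pi = 2), name = "inorganic pyrophosphatase"),
    # ---- glycolysis and anaplerosis
    rx("Vpfk", c(f6p = -1, atp = -1, fbp = 1, adp = 1), name = "ATP-phosphofructokinase"),
    rx("Vpfp", c(f6p = -1, ppi = -1, fbp = 1, pi = 1), rev = TRUE,
       name = "PPi-phosphofructokinase"),
    rx("Vfbpase", c(fbp = -1, f6p = 1, pi = 1), name = "fructose 1,6-bisphosphatase"),
    rx("Vald", c(fbp = -1, gap = 2), rev = TRUE, name = "aldolase + triose-P isomerase"),
    rx("Vgap", c(gap = -1, nad = -1, adp = -1, pi = -1, pg3 = 1, nadh = 1, atp = 1),
       rev = TRUE, name = "GAPDH + phosphoglycerate kinase"),
    rx("Veno", c(pg3 = -1, pep = 1), rev = TRUE, name = "PGM + enolase"),
    rx("Vpk", c(pep = -1, adp = -1, pyr = 1, atp = 1), name = "pyruvate kinase"),
    rx("Vpepc", c(pep = -1, co2 = -1, oaa = 1, pi = 1), name = "PEP carboxylase"),
    rx("Vme", c(mal = -1, nadp = -1, pyr = 1, co2 = 1, nadph = 1),
       name = "NADP-malic enzyme"),
    rx("Vpdh", c(pyr = -1, nad = -1, coa = -1, accoa = 1, co2 = 1, nadh = 1),
       name = "pyruvate dehydrogenase"),
    # ---- TCA cycle
    rx("Vcs", c(accoa = -1, oaa = -1, cit = 1, coa = 1), name = "citrate synthase"),
    rx("Vidh", c(cit = -1, nad = -1, akg = 1, co2 = 1, nadh = 1),
       name = "aconitase + isocitrate dehydrogenase"),
    rx("Vkgdh", c(akg = -1, nad = -1, adp = -1, pi = -1,
                  succ = 1, co2 = 1, nadh = 1, atp = 1),
       name = "2-oxoglutarate dehydrogenase + succinyl-CoA synthetase"),
    rx("Vsdh", c(succ = -1, fad = -1, fum = 1, fadh2 = 1), name = "succinate dehydrogenase"),
    rx("Vfum", c(fum = -1, mal = 1), rev = TRUE, name = "fumarase"),
    rx("Vmdh", c(mal = -1, nad = -1, oaa = 1, nadh = 1), rev = TRUE,
       name = "malate dehydrogenase"),
    rx("Vcitly", c(cit = -1, atp = -1, coa = -1, accoa = 1, oaa = 1, adp = 1, pi = 1),
       name = "ATP-citrate lyase"),
    # ---- pentose phosphate pathway
    rx("Vg6pdh", c(g6p = -1, nadp = -1, pg6 = 1, nadph = 1),
       name = "G6P dehydrogenase + lactonase"),
    rx("Vgnd", c(pg6 = -1, nadp = -1, ru5p = 1, co2 = 1, nadph = 1),
       name = "6-phosphogluconate dehydrogenase"),
    rx("Vrpi", c(ru5p = -1, r5p = 1), rev = TRUE, name = "ribose-5-phosphate isomerase"),
    rx("Vrpe", c(ru5p = -1, x5p = 1), rev = TRUE, name = "ribulose-5-phosphate epimerase"),
    rx("Vtkt1", c(r5p = -1, x5p = -1, s7p = 1, gap = 1), rev = TRUE, name = "transketolase 1"),
    rx("Vtal", c(s7p = -1, gap = -1, e4p = 1, f6p = 1), rev = TRUE, name = "transaldolase"),
    rx("Vtkt2", c(x5p = -1, e4p = -1, f6p = 1, gap = 1), rev = TRUE, name = "transketolase 2"),
    # ---- nitrate assimilation
    rx("Vnr", c(no3 = -1, nadh = -1, no2 = 1, nad = 1), name = "nitrate reductase"),
    rx("Vnir", c(no2 = -1, nadph = -3, nh4 = 1, nadp = 3), name = "nitrite reductase"),
    rx("Vgs", c(glu = -1, nh4 = -1, atp = -1, gln = 1, adp = 1, pi = 1),
       name = "glutamine synthetase"),
    rx("Vgogat", c(gln = -1, akg = -1, nadh = -1, glu = 2, nad = 1),
       name = "glutamate synthase (GOGAT)"),
    rx("Vgdh", c(akg = -1, nh4 = -1, nadh = -1, glu = 1, nad = 1),
       name = "glutamate dehydrogenase"),
    rx("Vaat", c(asp = -1, akg = -1, oaa = 1, glu = 1), rev = TRUE,
       name = "aspartate aminotransferase"),
    rx("Valat", c(ala = -1, akg = -1, pyr = 1, glu = 1), rev = TRUE,
       name = "alanine aminotransferase"),
    # ---- shikimate and phenylpropanoid pathway
    rx("Vshik", c(e4p = -1, pep = -2, nadph = -1, atp = -1,
                  chor = 1, nadp = 1, adp = 1, pi = 4),
       name = "shikimate pathway (DAHPS..CS lump)"),
    rx("Vphe", c(chor = -1, glu = -1, phe = 1, akg = 1, co2 = 1),
       name = "chorismate mutase + prephenate route to Phe"),
    rx("Vpal", c(phe = -1, cin = 1, nh4 = 1), name = "phenylalanine ammonia-lyase"),
    rx("Vcoum", c(cin = -1, nadph = -1, atp = -1, coa = -1,
                  coumcoa = 1, nadp = 1, amp = 1, ppi = 1),
       name = "C4H + 4-coumarate-CoA ligase"),
    rx("Vmacl", c(accoa = -1, co2 = -1, atp = -1, malcoa = 1, adp = 1, pi = 1),
       name = "acetyl-CoA carboxylase (malonyl-CoA supply)"),
    rx("Vchs", c(coumcoa = -1, malcoa = -3, chal = 1, coa = 4, co2 = 3),
       name = "chalcone synthase"),
    # ---- flavonoid core (the three reversible steps)
    rx("Vnar", c(chal = -1, nar = 1), rev = TRUE, name = "chalcone isomerase"),
    rx("Vdhq", c(nar = -1, akg = -1, dhq = 1, succ = 1, co2 = 1), rev = TRUE,
       name = "F3H + F3'H (2-OG dioxygenase)"),
    rx("Vlcc", c(dhq = -1, nadph = -1, lcc = 1, nadp = 1), rev = TRUE,
       name = "dihydroflavonol 4-reductase"),
    # ---- oxidative phosphorylation, adenylate kinase, maintenance
    rx("Vnrj1", c(nadh = -1, adp = -y1, pi = -y1, nad = 1, atp = y1),
       name = sprintf("NADH oxidation by respiratory chain (%.2g ATP/NADH)", y1)),
    rx("Vnrj2", c(fadh2 = -1, adp = -y2, pi = -y2, fad = 1, atp = y2),
       name = sprintf("FADH2 oxidation by respiratory chain (%.2g ATP/FADH2)", y2)),
    rx("Vadk", c(adp = -2, atp = 1, amp = 1), rev = TRUE, name = "adenylate kinase"),
    rx("Vnga-ATPm", c(atp = -1, adp = 1, pi = 1), kind = "maintenance",
       name = "non-growth-associated ATP maintenance"),
    # ---- simple accumulation fluxes (measured)
    rx("Vac-mal", c(mal = -1, mal_v = 1), kind = "exchange", name = "malate accumulation"),
    rx("Vac-glc", c(glc = -1, glc_v = 1), kind = "exchange", name = "glucose accumulation"),
    rx("Vac-fru", c(fru = -1, fru_v = 1), kind = "exchange", name = "fructose accumulation"),
    rx("Vac-suc", c(suc = -1, suc_v = 1), kind = "exchange", name = "sucrose accumulation"),
    rx("Vac-Glu", c(glu = -1, glu_v = 1), kind = "exchange", name = "glutamate accumulation"),
    rx("Vac-Asp", c(asp = -1, asp_v = 1), kind = "exchange", name = "aspartate accumulation"),
    rx("Vac-Ala", c(ala = -1, ala_v = 1), kind = "exchange", name = "alanine accumulation"),
    rx("Vac-Phe", c(phe = -1, phe_v = 1), kind = "exchange", name = "phenylalanine accumulation"),
    # ---- overall reactions to phenolic products (measured)
    rx("Vanthoc", c(lcc = -1, akg = -1, anthoc_b = 1, succ = 1, co2 = 1),
       kind = "overall", name = "anthocyanidin synthase (2-OG dioxygenase) + accumulation"),
    rx("Vflav", c(dhq = -1, akg = -1, flavonol_b = 1, succ = 1, co2 = 1),
       kind = "overall", name = "flavonol synthase (2-OG dioxygenase) + accumulation"),
    rx("Vtannins", c(lcc = -1, nadph = -1, tannin_b = 1, nadp = 1),
       kind = "overall", name = "LAR/ANR route to condensed tannins"),
    rx("Vstilb", c(coumcoa = -1, malcoa = -3, stilb_b = 1, coa = 4, co2 = 4),
       kind = "overall", name = "stilbene synthase"),
    # ---- overall biomass reactions (measured)
    rx("Vcw", c(g6p = -1, atp = -1, cw_b = 1, adp = 1, pi = 2),
       kind = "overall", name = "cell wall polysaccharide synthesis (via UDP-glucose)"),
    rx("Vprotein",
       c(glu = -pc[["glu"]], gln = -pc[["gln"]], asp = -pc[["asp"]],
         ala = -pc[["ala"]], phe = -pc[["phe"]],
         atp = -protein_atp, protein_b = 1, adp = protein_atp, pi = protein_atp),
       kind = "overall", name = "protein synthesis (per residue)"),
    rx("Vdag",
       c(gap = -1, pyr = -17, atp = -16, nadph = -31, nad = -17,
         dag_b = 1, co2 = 17, nadh = 17, nadp = 31, adp = 16, pi = 17),
       kind = "overall", name = "diacylglycerol synthesis (C16+C18 acyl chains)"),
    rx("Vnucleotides",
       c(r5p = -1, gln = -2, atp = -5, co2 = -1,
         nucl_b = 1, glu = 2, adp = 5, pi = 4),
       kind = "overall", name = "nucleotide (RNA+DNA) synthesis")
  )

  stoichiometric_network(
    mets, reactions,
    provenance = paste0(
      "GT3 curated reconstruction v1: central + polyphenol metabolism of a ",
      "Gamay Teinturier cell suspension; single-cell pooled compartments; ",
      sprintf("P/O NADH=%.3g FADH2=%.3g; ", p_o_nadh, p_o_fadh2),
      "stoichiometries from standard plant biochemistry (KEGG reference ",
      "stoichiometries); a user-supplied SBML model takes precedence over ",
      "this built-in when provided.")
  )
}

#' Reaction ids of the measured (fixed) exchange set
#'
#' The sixteen fluxes fixed by measured accumulation and biomass data: the
#' eight simple accumulation reactions and the eight overall
#' biomass/phenolic reactions.
#'
#' @return character vector of 16 reaction ids.
#' @export
gt3_measured_reactions <- function() {
  c("Vac-mal", "Vac-glc", "Vac-fru", "Vac-suc",
    "Vac-Glu", "Vac-Asp", "Vac-Ala", "Vac-Phe",
    "Vanthoc", "Vflav", "Vtannins", "Vstilb",
    "Vcw", "Vprotein", "Vdag", "Vnucleotides")
}
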