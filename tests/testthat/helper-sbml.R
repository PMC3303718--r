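# Hand-written SBML fixtures built in code (no binary data on disk).

write_fixture <- function(text, name, dir = tempfile("sbmlfx")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, name)
  writeLines(text, path)
  path
}

# A small ligand-receptor binding model: EGF + EGFR -> L_EGFR (re2),
# exercising name fallback, initial-value precedence, annotations under
# three qualifiers/syntaxes, local + global parameters, and an
# irreversible flag.
sbml_egfr_text <- function() {
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="egfr_binding" name="EGF-EGFR binding">
    <listOfCompartments>
      <compartment id="cell" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="EGF" name="Epidermal growth factor" compartment="cell" initialConcentration="2.5" initialAmount="99">
        <annotation>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
            <rdf:Description rdf:about="#EGF">
              <bqbiol:is><rdf:Bag><rdf:li rdf:resource="urn:miriam:uniprot:P01133"/></rdf:Bag></bqbiol:is>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
      <species id="EGFR" compartment="cell" initialAmount="7.125">
        <annotation>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
            <rdf:Description rdf:about="#EGFR">
              <bqbiol:is><rdf:Bag><rdf:li rdf:resource="http://identifiers.org/uniprot/P00533"/></rdf:Bag></bqbiol:is>
              <bqbiol:isVersionOf><rdf:Bag><rdf:li rdf:resource="urn:miriam:obo.go:GO%3A0004888"/></rdf:Bag></bqbiol:isVersionOf>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
      <species id="L_EGFR" compartment="cell">
        <annotation>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#">
            <rdf:Description rdf:about="#L_EGFR">
              <rdf:Bag><rdf:li rdf:resource="urn:miriam:testdb:COMPLEX1"/></rdf:Bag>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="kg" value="0.25"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="re2" reversible="false">
        <listOfReactants>
          <speciesReference species="EGF"/>
          <speciesReference species="EGFR"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="L_EGFR"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML"><apply><times/><ci> k1 </ci><ci> EGF </ci><ci> EGFR </ci></apply></math>
          <listOfParameters>
            <parameter id="k1" value="0.003"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>'
}

sbml_minimal_text <- function(model_id = "mini", species_block = "", reaction_block = "") {
  paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
         '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">\n',
         '  <model id="', model_id, '">\n',
         '    <listOfCompartments><compartment id="c"/></listOfCompartments>\n',
         species_block, reaction_block,
         '  </model>\n</sbml>')
}

# Assemble in-memory models without touching disk (uses the package's
# internal fixture constructors).
mem_model <- function(fullname, species, reactions) {
  pathblocks:::fx_model(fullname, species, reactions)
}
mem_species <- function(id, uri, initial = 1) {
  pathblocks:::fx_species(id, uri, initial)
}
mem_reaction <- function(id, reactants, products, k = 1, catalysts = character(0)) {
  pathblocks:::fx_reaction(id, reactants, products, k, catalysts)
}

# Species carrying several identity annotations.
structure_species_multi <- function(id, uris, initial = 1) {
  sp <- mem_species(id, uris[1], initial)
  sp$annotations <- lapply(uris, function(u) pathblocks:::make_annotation("is", u))
  sp
}
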