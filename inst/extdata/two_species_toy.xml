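<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic two-species toy model (ligand-reporter network), written by
     hand for the SBML import tests: same states, parameters, reactions and
     kinetic laws as ligand_reporter_problem()'s native model. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="two_species_toy" name="two-species ligand-reporter toy">
    <listOfCompartments>
      <compartment id="cell" size="1"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="x1" compartment="cell" initialConcentration="10"/>
      <species id="x2" compartment="cell" initialConcentration="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k1" value="0.02"/>
      <parameter id="k2" value="10"/>
      <parameter id="k3" value="1"/>
      <parameter id="k4" value="1"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="ligand_degradation" reversible="false">
        <listOfReactants>
          <speciesReference species="x1" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>k1</ci>
              <ci>x1</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="constitutive_production" reversible="false">
        <listOfProducts>
          <speciesReference species="x2" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <ci>k2</ci>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="ligand_driven_production" reversible="false">
        <listOfProducts>
          <speciesReference species="x2" stoichiometry="1"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>k3</ci>
              <ci>x1</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="reporter_degradation" reversible="false">
        <listOfReactants>
          <speciesReference species="x2" stoichiometry="1"/>
        </listOfReactants>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>k4</ci>
              <ci>x2</ci>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
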