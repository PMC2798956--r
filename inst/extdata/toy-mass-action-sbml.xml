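<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="toy_mass_action">
    <listOfSpecies>
      <species id="A" initialAmount="10"/>
      <species id="B" initialAmount="5"/>
      <species id="C" initialAmount="0"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="k2" value="2"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="bind" reversible="false">
        <listOfReactants>
          <speciesReference species="A"/>
          <speciesReference species="B"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k1</ci><ci>A</ci><ci>B</ci></apply>
          </math>
          <listOfLocalParameters>
            <localParameter id="k1" value="0.5"/>
          </listOfLocalParameters>
        </kineticLaw>
      </reaction>
      <reaction id="convert" reversible="false">
        <listOfReactants>
          <speciesReference species="A"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply><times/><ci>k2</ci><ci>A</ci></apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="source" reversible="false">
        <listOfProducts>
          <speciesReference species="A"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <cn>7</cn>
          </math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
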