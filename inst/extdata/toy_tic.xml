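<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      xmlns:groups="http://www.sbml.org/sbml/level3/version1/groups/version1"
      level="3" version="1" fbc:required="false" groups:required="false">
  <model id="toy_tic" name="Two-metabolite toy network with a thermodynamically infeasible cycle" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" name="cytosol" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="metabolite A" compartment="c" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"/>
      <species id="B" name="metabolite B" compartment="c" constant="false"
               boundaryCondition="false" hasOnlySubstanceUnits="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="bound_zero" value="0" constant="true"/>
      <parameter id="bound_upper" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g1" fbc:label="g1"/>
      <fbc:geneProduct fbc:id="G_g2" fbc:label="g2"/>
      <fbc:geneProduct fbc:id="G_g3" fbc:label="g3"/>
      <fbc:geneProduct fbc:id="G_g4" fbc:label="g4"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="v1" name="uptake of A" reversible="false" fast="false"
                fbc:lowerFluxBound="bound_zero" fbc:upperFluxBound="bound_upper">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g1"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="v2" name="A to B" reversible="false" fast="false"
                fbc:lowerFluxBound="bound_zero" fbc:upperFluxBound="bound_upper">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g2"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="v3" name="B to A" reversible="false" fast="false"
                fbc:lowerFluxBound="bound_zero" fbc:upperFluxBound="bound_upper">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g3"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="v4" name="secretion of B" reversible="false" fast="false"
                fbc:lowerFluxBound="bound_zero" fbc:upperFluxBound="bound_upper">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g4"/>
        </fbc:geneProductAssociation>
      </reaction>
    </listOfReactions>
    <groups:listOfGroups>
      <groups:group groups:id="exchange" groups:name="Exchange" groups:kind="partonomy">
        <groups:listOfMembers>
          <groups:member groups:idRef="v1"/>
          <groups:member groups:idRef="v4"/>
        </groups:listOfMembers>
      </groups:group>
      <groups:group groups:id="cycle" groups:name="Cycle" groups:kind="partonomy">
        <groups:listOfMembers>
          <groups:member groups:idRef="v2"/>
          <groups:member groups:idRef="v3"/>
        </groups:listOfMembers>
      </groups:group>
    </groups:listOfGroups>
  </model>
</sbml>
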