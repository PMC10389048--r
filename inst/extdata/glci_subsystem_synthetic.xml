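<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic SBML rendering of the bundled glucose subsystem of the yeast
     fermentation pathway. Hand-written illustrative fixture for the import
     hook; parameter values match beekin::default_truth(), not any published
     model. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="glci_subsystem_synthetic" name="Glucose subsystem (synthetic)">
    <listOfCompartments>
      <compartment id="cytoplasm" size="1" spatialDimensions="3" constant="true"/>
      <compartment id="extracellular" size="1" spatialDimensions="3" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="Glci" name="Glucose inside the cell" compartment="cytoplasm" initialConcentration="1"/>
      <species id="G6P" name="Glucose 6-phosphate" compartment="cytoplasm" initialConcentration="1" boundaryCondition="true"/>
      <species id="ATP" name="ATP" compartment="cytoplasm" initialConcentration="1" boundaryCondition="true"/>
      <species id="Glco" name="Glucose outside the cell" compartment="extracellular" initialConcentration="1" boundaryCondition="true"/>
      <species id="Gly" name="Glycerol" compartment="cytoplasm" initialConcentration="0" boundaryCondition="true"/>
      <species id="EtOH" name="Ethanol" compartment="cytoplasm" initialConcentration="0" boundaryCondition="true"/>
      <species id="Carbo" name="Glycogen and trehalose" compartment="cytoplasm" initialConcentration="0" boundaryCondition="true"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="Vin_Vm1" value="1.0"/>
      <parameter id="Vin_KilG6P" value="0.2"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="Vin" reversible="false">
        <listOfReactants>
          <speciesReference species="Glco"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Glci"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <times/>
              <ci>cytoplasm</ci>
              <apply>
                <minus/>
                <ci>Vin_Vm1</ci>
                <apply><times/><ci>Vin_KilG6P</ci><ci>G6P</ci></apply>
              </apply>
            </apply>
          </math>
        </kineticLaw>
      </reaction>
      <reaction id="Vhk" reversible="true">
        <listOfReactants>
          <speciesReference species="Glci"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="G6P"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">
            <apply>
              <divide/>
              <apply><times/><ci>cytoplasm</ci><ci>Vhk_Vm2</ci></apply>
              <apply>
                <plus/>
                <cn>1</cn>
                <apply><divide/><ci>Vhk_Km2Glc</ci><ci>Glci</ci></apply>
                <apply><divide/><ci>Vhk_Km2ATP</ci><ci>ATP</ci></apply>
                <apply>
                  <divide/>
                  <apply><times/><ci>Vhk_Ks2Glc</ci><ci>Vhk_Km2ATP</ci></apply>
                  <apply><times/><ci>Glci</ci><ci>ATP</ci></apply>
                </apply>
              </apply>
            </apply>
          </math>
          <listOfParameters>
            <parameter id="Vhk_Vm2" value="2.0"/>
            <parameter id="Vhk_Km2Glc" value="5.0"/>
            <parameter id="Vhk_Km2ATP" value="1.0"/>
            <parameter id="Vhk_Ks2Glc" value="0.5"/>
          </listOfParameters>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
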