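# Markups fiducial file version = 4.11
# CoordinateSystem = RAS
# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID
# SYNTHETIC template: AC and PC are the published template consensus values; the
# remaining 30 coordinates are plausible MNI placements constructed for simulation
# and testing only. They are NOT protocol consensus coordinates.
vtkMRMLMarkupsFiducialNode_1,-0.24,1.88,-4.75,0,0,0,1,1,1,0,AC,anterior commissure,
vtkMRMLMarkupsFiducialNode_2,-0.06,-24.68,-2.36,0,0,0,1,1,1,0,PC,posterior commissure,
vtkMRMLMarkupsFiducialNode_3,-0.10,-33.10,-13.20,0,0,0,1,1,1,0,ICS,infracollicular sulcus,
vtkMRMLMarkupsFiducialNode_4,-0.05,-36.40,-48.40,0,0,0,1,1,1,0,PMJ,pontomedullary junction,
vtkMRMLMarkupsFiducialNode_5,0.10,-13.90,-21.30,0,0,0,1,1,1,0,SIPF,superior interpeduncular fossa,
vtkMRMLMarkupsFiducialNode_6,8.20,-26.30,-18.10,0,0,0,1,1,1,0,RSLMS,right superior lateral mesencephalic sulcus,
vtkMRMLMarkupsFiducialNode_7,-8.20,-26.30,-18.10,0,0,0,1,1,1,0,LSLMS,left superior lateral mesencephalic sulcus,
vtkMRMLMarkupsFiducialNode_8,9.80,-31.20,-26.50,0,0,0,1,1,1,0,RILMS,right inferior lateral mesencephalic sulcus,
vtkMRMLMarkupsFiducialNode_9,-9.80,-31.20,-26.50,0,0,0,1,1,1,0,LILMS,left inferior lateral mesencephalic sulcus,
vtkMRMLMarkupsFiducialNode_10,0.20,-58.90,-1.30,0,0,0,1,1,1,0,CUL,culmen,
vtkMRMLMarkupsFiducialNode_11,0.00,-7.90,-15.60,0,0,0,1,1,1,0,IMS,intermammillary sulcus,
vtkMRMLMarkupsFiducialNode_12,2.70,-8.10,-15.20,0,0,0,1,1,1,0,RMB,right mammillary body,
vtkMRMLMarkupsFiducialNode_13,-2.70,-8.10,-15.20,0,0,0,1,1,1,0,LMB,left mammillary body,
vtkMRMLMarkupsFiducialNode_14,0.40,-31.80,-2.10,0,0,0,1,1,1,0,PG,pineal gland,
vtkMRMLMarkupsFiducialNode_15,15.80,3.50,16.10,0,0,0,1,1,1,0,RLVAC,right lateral ventricle at anterior commissure,
vtkMRMLMarkupsFiducialNode_16,-15.80,3.50,16.10,0,0,0,1,1,1,0,LLVAC,left lateral ventricle at anterior commissure,
vtkMRMLMarkupsFiducialNode_17,13.90,-27.20,18.70,0,0,0,1,1,1,0,RLVPC,right lateral ventricle at posterior commissure,
vtkMRMLMarkupsFiducialNode_18,-13.90,-27.20,18.70,0,0,0,1,1,1,0,LLVPC,left lateral ventricle at posterior commissure,
vtkMRMLMarkupsFiducialNode_19,0.20,29.90,4.30,0,0,0,1,1,1,0,GENU,genu of corpus callosum,
vtkMRMLMarkupsFiducialNode_20,0.10,-34.90,8.70,0,0,0,1,1,1,0,SPLE,splenium of corpus callosum,
vtkMRMLMarkupsFiducialNode_21,32.80,-6.30,-27.40,0,0,0,1,1,1,0,RALTH,right anterolateral temporal horn,
vtkMRMLMarkupsFiducialNode_22,-32.80,-6.30,-27.40,0,0,0,1,1,1,0,LALTH,left anterolateral temporal horn,
vtkMRMLMarkupsFiducialNode_23,25.10,-10.10,-17.90,0,0,0,1,1,1,0,RSAMTH,right superior anteromedial temporal horn,
vtkMRMLMarkupsFiducialNode_24,-25.10,-10.10,-17.90,0,0,0,1,1,1,0,LSAMTH,left superior anteromedial temporal horn,
vtkMRMLMarkupsFiducialNode_25,26.70,-8.80,-24.40,0,0,0,1,1,1,0,RIAMTH,right inferior anteromedial temporal horn,
vtkMRMLMarkupsFiducialNode_26,-26.70,-8.80,-24.40,0,0,0,1,1,1,0,LIAMTH,left inferior anteromedial temporal horn,
vtkMRMLMarkupsFiducialNode_27,2.50,11.90,14.10,0,0,0,1,1,1,0,RIGO,right indusium griseum origin,
vtkMRMLMarkupsFiducialNode_28,-2.50,11.90,14.10,0,0,0,1,1,1,0,LIGO,left indusium griseum origin,
vtkMRMLMarkupsFiducialNode_29,21.50,-81.00,4.30,0,0,0,1,1,1,0,RVOH,right ventral occipital horn,
vtkMRMLMarkupsFiducialNode_30,-21.50,-81.00,4.30,0,0,0,1,1,1,0,LVOH,left ventral occipital horn,
vtkMRMLMarkupsFiducialNode_31,7.20,17.90,-17.10,0,0,0,1,1,1,0,ROSF,right olfactory sulcal fundus,
vtkMRMLMarkupsFiducialNode_32,-7.20,17.90,-17.10,0,0,0,1,1,1,0,LOSF,left olfactory sulcal fundus,
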