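list(Age_Inheritance = 2, MetalIons = 2, APP = 2, Cytokines = 2, DailyActivities = 2, p53 = 2,
p.Age_Inheritance = c(0.57,0.43),
p.Ab = structure(.Data = c(0,1,0,1,0,1,0,1), .Dim = c(2,2,2)),
p.Tau_Phospho = structure(.Data = c(0,1,0,1), .Dim = c(2,2)),
p.MetalIons = c(0.76, 0.24),
p.LewyBodies = structure(.Data = c(0.884,0.116,0.884,0.116), .Dim = c(2,2)),
p.Hypertension = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.Depression = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.Smoking = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.Diabetes = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.Obesity = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.PhysicalActivity = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.APP = c(0.50,0.50),
p.GTP = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.APOE4 = structure(.Data = c(0.30,0.70,0.30,0.70), .Dim = c(2,2)),
p.PS1_2 = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.Cytokines = c(1,0),
p.SenilePlaques = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Unbalance_Ca = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Vascular = structure(.Data = c(0,1,0,1,0,1,0,1), .Dim = c(2,2,2)),
p.LogopenicAphasiaCortexAtrophy = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.MemoryHippocampalLoss = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.ExecLangPrax = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.VisualNeuropsychiatric = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.DailyActivities = c(0,1),
p.OxidStress1 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.OxidStress2 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Inflamation1 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Inflamation2 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Isoprostanes1 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Isoprostanes2 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Mito1 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Mito2 = structure(.Data = c(1,0,1,0,1,0,1,0), .Dim = c(2,2,2)),
p.Mito3 = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.MFN1 = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.OPA1 = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.DVLP = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.FIS1 = structure(.Data = c(1,0,1,0), .Dim = c(2,2)),
p.p53 = c(0.75,0.25),
p.Ab_APP = structure(.Data = c(0,1,0,1), .Dim = c(2,2)),
p.miRNAs = structure(.Data = c(0,1,0,1), .Dim = c(2,2)),
p.MCI_due_to_DayLiving = structure(.Data = c(1,0,1,0), .Dim = c(2,2)))
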